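Package: MetNetSim
Title: Network-Based Prediction of Treatment-Specific Metabolic Activity
    of Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts treatment-specific metabolic activity of microbial
    communities from tables of differentially abundant enzymes (EC
    numbers). Enzymes are mapped to directed reactions from a flat-file
    reaction database, metabolite graphs are built for the full community
    (meta-network) and for each treatment, environmental resource
    compounds (seed sets) are predicted from source components of the
    strongly-connected-component condensation, community metabolism is
    simulated by the network-expansion fixed point, and treatment-unique
    compounds are reported together with Fisher-exact pathway enrichment
    (Benjamini-Hochberg FDR) and force-directed network visualizations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ingest.R'
    'reactiondb.R'
    'fixture.R'
    'netgraph.R'
    'seeds.R'
    'expansion.R'
    'enrichment.R'
    'viz.R'
    'pipeline.R'
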