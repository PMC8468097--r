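#' Create a pipeline configuration
#'
#' @param inputPath path to the differential enzyme table.
#' @param databasePaths named character/list with \code{reactions},
#'   \code{compounds} and optionally \code{compound_pathways},
#'   \code{ec_pathways}.
#' @param outputDir output directory (created if needed).
#' @param treatmentLabels character(2) display names; substituted into
#'   output file names (defaults keep the generic
#'   \code{treatment_1}/\code{treatment_2} naming).
#' @param minPathwaySize,maxPathwaySize pathway size window for
#'   enrichment.
#' @param excludedPathways pathways excluded from enrichment testing.
#' @param alpha FDR significance threshold.
#' @param hubMaxNeighbors visualization hub filter threshold.
#' @param layoutIterations Fruchterman-Reingold iterations.
#' @param rngSeed seed for all stochastic steps.
#' @param auxiliarySeedCompounds compounds added to every expansion
#'   seed set (default empty).
#' @param palette display colors, see [defaultPalette()].
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(inputPath, databasePaths, outputDir,
        treatmentLabels = c("treatment_1", "treatment_2"),
        minPathwaySize = 1, maxPathwaySize = Inf,
        excludedPathways = character(0), alpha = 0.05,
        hubMaxNeighbors = 25, layoutIterations = 50, rngSeed = 0,
        auxiliarySeedCompounds = character(0),
        palette = defaultPalette()) {
    new("PipelineConfig", inputPath = inputPath,
        databasePaths = unlist(databasePaths), outputDir = outputDir,
        treatmentLabels = as.character(treatmentLabels),
        minPathwaySize = minPathwaySize, maxPathwaySize = maxPathwaySize,
        excludedPathways = excludedPathways, alpha = alpha,
        hubMaxNeighbors = hubMaxNeighbors,
        layoutIterations = layoutIterations, rngSeed = rngSeed,
        auxiliarySeedCompounds = auxiliarySeedCompounds,
        palette = palette)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

.writeEnrichmentCsv <- function(enr, mapping, path) {
    out <- enr
    out$p_value <- .fmtNum(out$p_value, 10)
    out$q_value <- .fmtNum(out$q_value, 10)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    mpath <- sub("\\.csv$", "_mapping.csv", path)
    utils::write.csv(mapping, mpath, row.names = FALSE, quote = TRUE)
    c(path, mpath)
}

#' Run the full analysis pipeline
#'
#' Executes the complete flow: parse the differential enzyme table;
#' build the meta-network and the two treatment sub-networks; predict
#' environmental resources by SCC-condensation source detection and
#' intersect each treatment's seeds with the meta-network seeds;
#' simulate both treatments by network expansion over the identical
#' meta reaction bank; derive treatment-unique compounds; run Fisher
#' pathway enrichment for three entity classes (differential enzymes,
#' environmental resources, unique expansion compounds) per treatment;
#' and render hub-filtered, force-directed network visualizations with
#' enriched-pathway halos and per-pathway sub-graph exports. All
#' outputs use fixed names (with the treatment display labels
#' substituted) and a JSON manifest records the configuration,
#' universe definitions and file list; identical configuration and
#' inputs yield byte-identical text outputs.
#'
#' Enrichment universes: enzymes are tested against all ECs of the
#' input table; environmental resources against the meta-network seed
#' set; unique expansion compounds against the compounds producible
#' from the union of both environment proxies over the meta bank.
#'
#' @param config a [PipelineConfig-class].
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
    validObject(config)
    for (f in c(config@inputPath, config@databasePaths))
        if (!file.exists(f))
            .stopf("[input] file does not exist: %s", f)
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    labels <- config@treatmentLabels
    files <- character(0)
    warningsLog <- character(0)
    noteWarning <- function(w) {
        warningsLog <<- c(warningsLog, conditionMessage(w))
        invokeRestart("muffleWarning")
    }
    out <- function(...) file.path(config@outputDir, paste0(...))

    tab <- .stage("ingest", parseDifferentialTable(config@inputPath,
        treatmentLabels = labels))
    db <- .stage("reactiondb",
        loadReactionDatabase(config@databasePaths))
    summ <- summarizeTable(tab)
    files <- c(files, writeSummaryJson(summ, out("input_summary.json")))
    files <- c(files, plotSummary(summ, out("input_summary.png")))

    ecsets <- scopeEcSets(tab)
    nets <- .stage("netgraph", withCallingHandlers(
        list(meta = buildNetwork(db, ecsets$meta, "meta"),
            treatment_1 = buildNetwork(db, ecsets$treatment_1, "treatment_1"),
            treatment_2 = buildNetwork(db, ecsets$treatment_2, "treatment_2")),
        warning = noteWarning))
    for (s in names(nets))
        files <- c(files, exportNetwork(nets[[s]],
            out(labels[match(s, c("treatment_1", "treatment_2"))] %|na|% s,
                "_edgelist.tsv"),
            out(labels[match(s, c("treatment_1", "treatment_2"))] %|na|% s,
                "_nodelist.tsv")))

    proxies <- .stage("seeds", withCallingHandlers({
        metaProxy <- detectSeeds(nets$meta)
        p1 <- applyMetaFilter(detectSeeds(nets$treatment_1), metaProxy)
        p2 <- applyMetaFilter(detectSeeds(nets$treatment_2), metaProxy)
        list(meta = metaProxy, treatment_1 = p1, treatment_2 = p2)
    }, warning = noteWarning))
    files <- c(files,
        writeResourceList(proxies$treatment_1, out(labels[1], "_resources.txt")),
        writeResourceList(proxies$treatment_2, out(labels[2], "_resources.txt")))

    expansions <- .stage("expansion", simulateTreatments(db, ecsets$meta,
        proxies$treatment_1, proxies$treatment_2,
        config@auxiliarySeedCompounds))
    uniq <- uniqueCompounds(expansions$treatment_1, expansions$treatment_2)
    files <- c(files,
        writeCompoundList(uniq$treatment_1, out(labels[1], "_compounds.txt")),
        writeCompoundList(uniq$treatment_2, out(labels[2], "_compounds.txt")))

    # enrichment universes (documented defaults)
    unionProxy <- unique(c(proxies$treatment_1@compounds,
        proxies$treatment_2@compounds,
        config@auxiliarySeedCompounds))
    metaBank <- ecToReactions(db, ecsets$meta)
    unionExpansion <- expandNetwork(metaBank, unionProxy, "meta")
    universes <- list(
        enzyme = ecsets$meta,
        resource = proxies$meta@compounds,
        compound = unionExpansion@producible)

    enrTables <- list()
    enrich <- function(entities, class, label, fileStem) {
        map <- if (class == "enzyme") db@ecPathways else db@compoundPathways
        enr <- fisherPathwayEnrichment(entities, universes[[class]], map,
            minSize = config@minPathwaySize, maxSize = config@maxPathwaySize,
            excluded = config@excludedPathways, alpha = config@alpha)
        mapping <- pathwayTable(entities, map)
        files <<- c(files, .writeEnrichmentCsv(enr, mapping, out(fileStem)))
        enrTables[[paste(label, class, sep = ".")]] <<- enr
        enr
    }
    enr <- .stage("enrichment", list(
        t1_enzymes = enrich(ecsets$treatment_1, "enzyme", labels[1],
            paste0(labels[1], "_Enzymes_pathway.csv")),
        t2_enzymes = enrich(ecsets$treatment_2, "enzyme", labels[2],
            paste0(labels[2], "_Enzymes_pathway.csv")),
        t1_resources = enrich(proxies$treatment_1@compounds, "resource",
            labels[1], paste0(labels[1], "_resources_pathway.csv")),
        t2_resources = enrich(proxies$treatment_2@compounds, "resource",
            labels[2], paste0(labels[2], "_resources_pathway.csv")),
        t1_compounds = enrich(uniq$treatment_1, "compound", labels[1],
            paste0(labels[1], "_compounds_pathway.csv")),
        t2_compounds = enrich(uniq$treatment_2, "compound", labels[2],
            paste0(labels[2], "_compounds_pathway.csv"))))

    .stage("viz", for (i in 1:2) {
        scope <- paste0("treatment_", i)
        expd <- expansions[[scope]]
        rx <- metaBank[metaBank$reaction_id %in% expd@firedReactions, ,
            drop = FALSE]
        expNet <- metabolicNetwork(.reactionEdges(rx), scope)
        visNet <- filterHubs(expNet, config@hubMaxNeighbors)
        roles <- assignRoles(visNet, proxies[[scope]], uniq[[scope]],
            ecsets[[scope]])
        enriched <- enr[[paste0("t", i, "_compounds")]]
        enrichedPw <- enriched$pathway[enriched$enriched]
        halos <- lapply(stats::setNames(visNet@nodes, visNet@nodes),
            function(nd) {
                if (!(nd %in% uniq[[scope]])) return(character(0))
                intersect(db@compoundPathways[[nd]] %||% character(0),
                    enrichedPw)
            })
        lay <- suppressMessages(layoutNetwork(visNet, dims = 3,
            iterations = config@layoutIterations,
            rngSeed = config@rngSeed + i,
            nodeRoles = roles$nodeRoles, edgeRoles = roles$edgeRoles,
            haloPathways = halos))
        files <- c(files, renderNetwork(lay, visNet,
            out(labels[i], "_network.png"),
            out("3D_network_", labels[i], ".json"),
            palette = config@palette))
        files <- c(files, exportPathwaySubgraphs(lay, visNet, enrichedPw,
            db@compoundPathways, config@outputDir, labels[i]))
    })

    manifest <- list(
        package = "MetNetSim",
        version = as.character(utils::packageVersion("MetNetSim")),
        config = list(
            input = config@inputPath,
            database = as.list(config@databasePaths),
            treatment_labels = labels,
            min_pathway_size = config@minPathwaySize,
            max_pathway_size = if (is.finite(config@maxPathwaySize))
                config@maxPathwaySize else "Inf",
            excluded_pathways = config@excludedPathways,
            alpha = config@alpha,
            hub_max_neighbors = config@hubMaxNeighbors,
            layout_iterations = config@layoutIterations,
            rng_seed = config@rngSeed,
            auxiliary_seed_compounds = config@auxiliarySeedCompounds),
        universes = list(
            enzyme = "all ECs of the input table",
            resource = "seed compounds of the meta-network",
            compound = "meta-bank expansion closure of the union of both proxies",
            sizes = lapply(universes, length)),
        counts = list(
            enzymes = nrow(tab@records),
            meta_nodes = length(nets$meta@nodes),
            meta_edges = nrow(nets$meta@edges),
            meta_seeds = length(proxies$meta@compounds),
            treatment_1_resources = length(proxies$treatment_1@compounds),
            treatment_2_resources = length(proxies$treatment_2@compounds),
            treatment_1_unique_compounds = length(uniq$treatment_1),
            treatment_2_unique_compounds = length(uniq$treatment_2)),
        warnings = warningsLog,
        files = sort(basename(files)))
    jsonlite::write_json(manifest, file.path(config@outputDir,
        "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

# label lookup helper: NA (scope "meta") falls back to the scope name
`%|na|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
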