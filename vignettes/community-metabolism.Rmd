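---
title: "Predicting community metabolism from differential enzyme abundance"
author: "MetNetSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting community metabolism from differential enzyme abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetNetSim)
```

## The model

MetNetSim treats a microbial community as a single pooled metabolic
network. The input is not gene counts but the *output of* a
differential-abundance analysis: one record per EC number with a log2
fold change, raw and adjusted p-values, and a three-way label
(treatment 1, treatment 2, not associated). The package deliberately
does not recompute differential abundance — that model (edgeR-style
count modelling) lives upstream, and the table is taken as
authoritative, including any upstream choices about collapsing
conflicting annotations across contigs.

Three assumptions shape everything downstream:

* **Presence/absence chemistry.** A reaction either can or cannot
  proceed; stoichiometry, rates and thermodynamics are ignored. This is
  the classical network-expansion contract: once a compound is
  produced it remains available.
* **Directionality by splitting.** The condensation and expansion
  semantics need explicit edge direction, so a reversible reaction is
  materialized as two independent directed reactions (`_f`/`_r`). Each
  half fires on its own. Whether the historical KEGG-derived schemes
  treated reversibility this way is not documented; the split is this
  package's convention and is stated on the `ReactionDatabase` class.
* **Community pooling.** All enzymes act in one compartment: the
  simulation cannot distinguish cross-feeding between taxa from
  intracellular chains.

### Seed detection

On the compound graph (substrate → product edges, merged witnesses,
self-pairs dropped) the strongly connected components are computed and
contracted. A component with no incoming edge from another component is
a *source component*; its members cannot be produced by the network and
are predicted environmental resources. All members of a multi-node
source component are reported — the package does not down-weight by
component size as some reverse-ecology work does, because the output
contract is a plain compound list; the component id and size are kept
in the proxy's provenance so users can post-filter. Two consequences
worth knowing: every node of the network is reachable from the seed
set, and the condensation is acyclic — both are asserted in the test
suite on randomized graphs.

Treatment sub-networks are built from differential enzymes only and are
therefore fragmented; chains that are internally complete in the
community appear broken, and their interior compounds would surface as
spurious sources. The meta filter removes them: a treatment's
environment proxy is the intersection of its own seed set with the
meta-network seed set. On randomized edge-deleted sub-networks the raw
seed count is never below the filtered count, which is the behaviour
the filter exists to correct.

### Expansion

`expandNetwork()` computes the least fixed point by rounds: fire every
unfired reaction whose full substrate set is in the pool, add the
products, repeat. The implementation keeps a per-reaction count of
unmet substrates so each compound arrival does constant work per
consuming reaction; results are provably order-invariant, monotone in
the seed set, idempotent, and terminate within one round per reaction.
Both treatments expand over the *identical* meta reaction bank — all
reactions of all input ECs — so the difference between closures
isolates the effect of the predicted environments. By default nothing
beyond the environment proxy seeds the expansion: no cofactor or
currency-metabolite amnesty. Real communities obviously have water and
phosphate; if a user wants them available they can be injected
explicitly via `auxiliarySeedCompounds`, which exists for sensitivity
analyses and defaults to empty so results are a pure function of
topology.

### Enrichment

Enrichment of a query set within a universe is the one-sided Fisher
exact (hypergeometric upper-tail) probability of at least the observed
overlap, BH-adjusted over exactly the set of tested pathways, enriched
at q ≤ 0.05. A pathway is tested only when its size *within the
universe* falls in `[minPathwaySize, maxPathwaySize]`, it is not
excluded by name, and the query hits it at least once; measuring size
within the universe keeps the size filter and the test in a single
sampling frame. The universes are a genuinely open design point — no
published convention pins them down — and the package fixes documented
defaults: all input ECs for enzymes; meta-network seeds for resources;
and for unique compounds, the closure of the meta bank expanded from
the *union* of both proxies (the pool either treatment could in
principle produce). Each is recorded in the run manifest.

### Visualization

Hub compounds with more than 25 distinct neighbors (undirected,
multiplicity-free) are removed in a single pass before layout — degrees
are measured once on the input graph, never recomputed, so removal
cannot cascade. The boundary is sharp: 25 neighbors is kept, 26 is
removed. Layouts are Fruchterman–Reingold from a seeded uniform start,
so a fixed `rngSeed` gives byte-identical coordinate exports;
`iterations = 0` returns the raw seeded placement. Interactive 3-D
widgets are intentionally out of scope; the 3-D product is a JSON
nodes/edges/coordinates/roles export any front-end can render, and each
enriched pathway additionally gets an induced sub-graph export indexed
`0..k-1` in enrichment order.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `minPathwaySize`, `maxPathwaySize` | 1, Inf | entities per pathway in the universe | small pathways are unstable under Fisher, huge umbrella pathways dilute signal; the window is user scientific judgement |
| `alpha` | 0.05 | FDR scale | enrichment is flagged on adjusted values |
| `hubMaxNeighbors` | 25 | distinct neighbors | visualization-only currency filter; analysis graphs keep hubs |
| `layoutIterations` | 50 | iterations | force-layout convergence vs time |
| `rngSeed` | 0 | integer | only source of randomness (layout) |
| `auxiliarySeedCompounds` | empty | compound ids | sensitivity studies; empty keeps predictions purely topological |

The hub threshold applies only at the visualization stage; a
construction-time pre-filter exists as an option for sensitivity
analysis but defaults to off, because removing hubs before seed
detection changes the topology the predictions rest on.

## The synthetic-data generator

`generateFixtureDatabase()` builds databases whose correct answers are
known by construction, not by running the detector: a set of source
compounds that no reaction ever produces, a producing skeleton in which
every other compound is made from strictly earlier compounds (so the
closure from the sources is the whole compound set), then cycles and
reversible lateral conversions placed so that every non-trivial
strongly connected component keeps an incoming edge from outside
itself. The planted sources are therefore provably the exact source
components, whatever the random draws. Default shape: 15% of compounds
are sources, 25% of extra reactions reversible, 1–2 substrates per
reaction, pathway labels scattered 0–2 per entity — values chosen to
resemble a mid-density metabolic scheme rather than any particular
KEGG snapshot.

What it does *not* emulate: realistic pathway structure (annotations
are random, so enrichment on fixtures exercises the counting and the
test, not biology), realistic degree distributions (no water-like
mega-hubs), partial EC annotations, or compounds produced by nothing
and consumed by nothing. Passing tests on fixtures therefore validate
the algorithms' contracts, not the ecological interpretation of any
real dataset.

`generateFixtureTable()` completes the synthetic study: every database
EC receives an association label (defaults 30/30/40%), with
differential enzymes given |logFC| ≥ 2 and adjusted p < 0.015, and the
rest near-null statistics — the shape of a typical edgeR contrast after
filtering.

## Numerical and degenerate-input choices

* Empty networks yield empty proxies; expansion from empty seeds gives
  an empty closure; both are contracts, not errors. An EC set matching
  no reaction returns an empty network with a warning recorded in the
  object and the run manifest.
* Fisher p-values come from the exact hypergeometric tail
  (`phyper`), not a normal approximation; the suite checks them
  against explicit binomial-coefficient sums to 1e-10 for all table
  sizes up to N = 60.
* Enrichment rows sort by q, then p, then pathway name — the last key
  makes output order total and reruns byte-identical.
* Duplicate ECs in the input are a hard error rather than being
  merged: a differential classification must be unambiguous per EC.
* The parser auto-detects comma/tab/semicolon, strips `ec:` prefixes,
  and accepts association synonyms including the user's display names,
  because upstream tools are inconsistent on all three.
* All stochastic steps run under a locally seeded RNG that restores
  the caller's RNG state, so library calls never perturb user
  workflows.

## Problem sizes used by the shipped checks

The test suite validates against brute-force oracles at sizes where the
oracles are comfortably exact: random digraphs up to 200 nodes against
a matrix transitive-closure seed rule, 100 random reaction banks up to
300 reactions against a loop-until-stable expansion oracle under 10
bank permutations each, exhaustive hypergeometric enumeration up to
N = 60, and 50 planted-ground-truth databases. The acceptance script
runs the full pipeline at 200 compounds / 320 reactions. These sizes
are the package's own validation design; the algorithms themselves are
near-linear (SCC, expansion) and run comfortably on databases with
thousands of reactions.

## Known limitations

* Exact EC matching only: a partial EC such as `1.1.1.-` maps to a
  reaction only if the database annotates that exact string; unmatched
  ECs are logged, never expanded to all completions.
* No flux, mass balance, or thermodynamics; "producible" means
  reachable under set semantics.
* Pooled-community modelling cannot attribute activity to taxa or
  detect obligate cross-feeding.
* Enrichment inherits every bias of the pathway annotation; the
  unannotated fraction is visible in the mapping tables.
* The seed rule reports all members of a multi-node source cycle,
  which can overstate the environment when a large cycle sits at the
  top of the network; the provenance component size is the handle for
  screening such cases.
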