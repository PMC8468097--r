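#' @import methods
NULL

.SCOPE_LEVELS <- c("meta", "treatment_1", "treatment_2")
.ASSOCIATION_LEVELS <- c("treatment_1", "treatment_2", "not_associated")

#' DifferentialEnzymeTable: per-EC differential-abundance records
#'
#' Holds one record per enzyme (EC number) from an upstream differential
#' abundance analysis (e.g. edgeR applied to functionally annotated
#' metagenomic reads), together with the display names of the two
#' treatments being contrasted.
#'
#' @slot records data.frame with columns \code{ec_id} (character),
#'   \code{log_fc} (numeric, log2 fold change), \code{p_value},
#'   \code{adj_p_value} (numeric in [0,1]) and \code{association}
#'   (factor with levels \code{treatment_1}, \code{treatment_2},
#'   \code{not_associated}). Row order is input file order.
#' @slot treatmentLabels character(2), display names of the two
#'   treatments (e.g. \code{c("root", "soil")}).
#'
#' @seealso [parseDifferentialTable()], [summarizeTable()]
#' @exportClass DifferentialEnzymeTable
setClass("DifferentialEnzymeTable",
    representation(records = "data.frame", treatmentLabels = "character"))

setValidity("DifferentialEnzymeTable", function(object) {
    rec <- object@records
    need <- c("ec_id", "log_fc", "p_value", "adj_p_value", "association")
    if (!all(need %in% names(rec)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(rec) < 1L)
        return("table must contain at least one record")
    if (anyDuplicated(rec$ec_id))
        return(paste("duplicate ec_id:",
            paste(unique(rec$ec_id[duplicated(rec$ec_id)]), collapse = ", ")))
    if (!all(grepl(.EC_PATTERN, rec$ec_id)))
        return("ec_id values must match the dotted EC pattern a.b.c.d")
    for (col in c("p_value", "adj_p_value")) {
        v <- rec[[col]]
        if (any(!is.finite(v) | v < 0 | v > 1))
            return(paste(col, "must lie in [0, 1]"))
    }
    if (!all(as.character(rec$association) %in% .ASSOCIATION_LEVELS))
        return("association must be treatment_1, treatment_2 or not_associated")
    if (length(object@treatmentLabels) != 2L)
        return("treatmentLabels must have length 2")
    TRUE
})

#' ReactionDatabase: EC-to-reaction mapping with pathway annotations
#'
#' A KEGG-like reaction scheme: directed reactions (reversible reactions
#' are materialized as two directed entries with suffixes \code{_f} and
#' \code{_r}), compound display names, and compound/EC-to-pathway
#' annotation maps. Chemistry is presence/absence: stoichiometric
#' coefficients are not represented.
#'
#' @slot reactions data.frame with columns \code{reaction_id},
#'   \code{base_id}, \code{reversible} (logical) and list-columns
#'   \code{ec}, \code{substrates}, \code{products}.
#' @slot compoundNames named character, compound id -> display name.
#' @slot compoundPathways named list, compound id -> character vector of
#'   pathway names (may be partial).
#' @slot ecPathways named list, EC -> character vector of pathway names.
#' @slot allowSelfConversion logical; if FALSE (default) a reaction may
#'   not list the same compound as both substrate and product.
#'
#' @seealso [loadReactionDatabase()], [ecToReactions()],
#'   [generateFixtureDatabase()]
#' @exportClass ReactionDatabase
setClass("ReactionDatabase",
    representation(reactions = "data.frame", compoundNames = "character",
        compoundPathways = "list", ecPathways = "list",
        allowSelfConversion = "logical"))

setValidity("ReactionDatabase", function(object) {
    rx <- object@reactions
    need <- c("reaction_id", "base_id", "ec", "substrates", "products",
        "reversible")
    if (!all(need %in% names(rx)))
        return(paste("reactions must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(rx$reaction_id))
        return("reaction_id values must be unique")
    if (nrow(rx) > 0L) {
        ns <- lengths(rx$substrates)
        np <- lengths(rx$products)
        if (any(ns == 0L) || any(np == 0L))
            return("substrate and product lists must be non-empty")
        if (!isTRUE(object@allowSelfConversion)) {
            ov <- mapply(function(s, p) length(intersect(s, p)) > 0L,
                rx$substrates, rx$products)
            if (any(ov))
                return(paste("substrates and products overlap in:",
                    paste(rx$reaction_id[ov], collapse = ", ")))
        }
        cpds <- unique(c(unlist(rx$substrates), unlist(rx$products)))
        miss <- setdiff(cpds, names(object@compoundNames))
        if (length(miss))
            return(paste("compounds referenced but not declared:",
                paste(miss, collapse = ", ")))
    }
    TRUE
})

#' MetabolicNetwork: directed metabolite graph
#'
#' Nodes are compounds; a directed edge substrate -> product is present
#' whenever some selected reaction consumes the substrate and produces
#' the product. Each edge carries witness sets of the (reaction, EC)
#' pairs that induced it; parallel witnesses are merged onto one edge.
#' Self-loops are never created.
#'
#' @slot nodes character, compound ids (exactly the edge endpoints).
#' @slot edges data.frame with columns \code{substrate}, \code{product}
#'   and list-columns \code{reactions}, \code{ecs} (witnesses).
#' @slot scopeLabel one of \code{"meta"}, \code{"treatment_1"},
#'   \code{"treatment_2"}.
#' @slot unmatchedEcs character, query ECs that mapped to no reaction.
#'
#' @seealso [buildNetwork()], [detectSeeds()], [filterHubs()]
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
    representation(nodes = "character", edges = "data.frame",
        scopeLabel = "character", unmatchedEcs = "character"))

setValidity("MetabolicNetwork", function(object) {
    ed <- object@edges
    need <- c("substrate", "product", "reactions", "ecs")
    if (!all(need %in% names(ed)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (!object@scopeLabel %in% .SCOPE_LEVELS)
        return("scopeLabel must be meta, treatment_1 or treatment_2")
    if (nrow(ed) > 0L) {
        if (any(ed$substrate == ed$product))
            return("self-loop edges are not allowed")
        if (!all(c(ed$substrate, ed$product) %in% object@nodes))
            return("every edge endpoint must be a node")
        if (any(lengths(ed$reactions) == 0L) || any(lengths(ed$ecs) == 0L))
            return("edge witness sets must be non-empty")
    }
    TRUE
})

#' EnvironmentalProxy: predicted environmental resource compounds
#'
#' The seed set of a metabolic network: compounds the community cannot
#' produce internally and must acquire from the environment.
#' Topologically these are the members of source components of the SCC
#' condensation. For a treatment sub-network the proxy becomes usable
#' only after intersection with the meta-network seed set
#' (\code{filtered = TRUE}); the sub-networks are fragmented and on
#' their own predict artificial source metabolites.
#'
#' @slot compounds character, seed compound ids.
#' @slot provenance data.frame with columns \code{compound},
#'   \code{scc_id}, \code{scc_size} for every seed compound.
#' @slot scopeLabel scope of the originating network.
#' @slot filtered logical, TRUE after [applyMetaFilter()].
#'
#' @seealso [detectSeeds()], [applyMetaFilter()]
#' @exportClass EnvironmentalProxy
setClass("EnvironmentalProxy",
    representation(compounds = "character", provenance = "data.frame",
        scopeLabel = "character", filtered = "logical"))

setValidity("EnvironmentalProxy", function(object) {
    pv <- object@provenance
    if (!all(c("compound", "scc_id", "scc_size") %in% names(pv)))
        return("provenance must have columns compound, scc_id, scc_size")
    if (!setequal(pv$compound, object@compounds))
        return("provenance must cover exactly the proxy compounds")
    if (nrow(pv) > 0L && any(pv$scc_size < 1L))
        return("scc_size must be >= 1")
    if (!object@scopeLabel %in% .SCOPE_LEVELS)
        return("scopeLabel must be meta, treatment_1 or treatment_2")
    TRUE
})

#' ExpansionResult: fixed point of the network-expansion algorithm
#'
#' The closure of compounds producible from a seed set over a reaction
#' bank: reactions whose full substrate set is available fire and
#' contribute their products, iterating until no new reaction fires.
#'
#' @slot seeds character, the seed compounds the expansion started from.
#' @slot producible character, all producible compounds (includes seeds).
#' @slot firedReactions character, ids of reactions that fired.
#' @slot iterations list; element i is \code{list(reactions=, compounds=)},
#'   the reactions newly fired and compounds newly produced in round i.
#' @slot scopeLabel scope of the simulated treatment.
#'
#' @seealso [expandNetwork()], [simulateTreatments()], [uniqueCompounds()]
#' @exportClass ExpansionResult
setClass("ExpansionResult",
    representation(seeds = "character", producible = "character",
        firedReactions = "character", iterations = "list",
        scopeLabel = "character"))

setValidity("ExpansionResult", function(object) {
    if (!all(object@seeds %in% object@producible))
        return("seeds must be contained in producible")
    newc <- unlist(lapply(object@iterations, `[[`, "compounds"))
    if (anyDuplicated(newc))
        return("iteration compound layers must be disjoint")
    newr <- unlist(lapply(object@iterations, `[[`, "reactions"))
    if (anyDuplicated(newr))
        return("iteration reaction layers must be disjoint")
    if (!setequal(newr, object@firedReactions))
        return("iteration layers must partition firedReactions")
    TRUE
})

#' NetworkLayout: node coordinates and display roles for rendering
#'
#' @slot positions numeric matrix (nodes x 2 or 3), rownames are node ids.
#' @slot nodeRoles named character; one of \code{seed},
#'   \code{treatment_unique}, \code{shared} per retained node.
#' @slot edgeRoles character per edge row of the laid-out network;
#'   \code{differential} or \code{background}.
#' @slot haloPathways named list, node -> enriched pathway names drawn
#'   as background halos.
#' @slot rngSeed integer seed used for the force-directed layout.
#' @slot iterations number of Fruchterman-Reingold iterations.
#'
#' @seealso [layoutNetwork()], [assignRoles()], [renderNetwork()]
#' @exportClass NetworkLayout
setClass("NetworkLayout",
    representation(positions = "matrix", nodeRoles = "character",
        edgeRoles = "character", haloPathways = "list",
        rngSeed = "numeric", iterations = "numeric"))

setValidity("NetworkLayout", function(object) {
    if (!ncol(object@positions) %in% c(2L, 3L))
        return("positions must have 2 or 3 columns")
    if (any(!is.finite(object@positions)))
        return("positions must be finite")
    if (nrow(object@positions) > 0L && is.null(rownames(object@positions)))
        return("positions must have node rownames")
    TRUE
})

#' PipelineConfig: configuration of a full analysis run
#'
#' @slot inputPath path to the differential enzyme table.
#' @slot databasePaths named character with elements \code{reactions},
#'   \code{compounds} and optionally \code{compound_pathways},
#'   \code{ec_pathways}.
#' @slot outputDir directory the output file set is written to.
#' @slot treatmentLabels character(2) display names substituted into
#'   output file names.
#' @slot minPathwaySize,maxPathwaySize pathway size window (entities per
#'   pathway within the universe) for enrichment testing.
#' @slot excludedPathways pathway names excluded from testing.
#' @slot alpha FDR significance threshold (default 0.05).
#' @slot hubMaxNeighbors visualization hub filter: nodes with more than
#'   this many distinct neighbors are dropped before layout (default 25).
#' @slot layoutIterations Fruchterman-Reingold iterations.
#' @slot rngSeed seed for all stochastic steps (layout).
#' @slot auxiliarySeedCompounds compounds added to every expansion seed
#'   set (default empty; the environment proxy alone seeds expansion).
#' @slot palette named character of display colors.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(inputPath = "character", databasePaths = "character",
        outputDir = "character", treatmentLabels = "character",
        minPathwaySize = "numeric", maxPathwaySize = "numeric",
        excludedPathways = "character", alpha = "numeric",
        hubMaxNeighbors = "numeric", layoutIterations = "numeric",
        rngSeed = "numeric", auxiliarySeedCompounds = "character",
        palette = "character"))

setValidity("PipelineConfig", function(object) {
    if (object@minPathwaySize > object@maxPathwaySize)
        return("minPathwaySize must be <= maxPathwaySize")
    if (object@minPathwaySize < 1)
        return("minPathwaySize must be >= 1")
    if (object@alpha <= 0 || object@alpha > 1)
        return("alpha must be in (0, 1]")
    if (length(object@treatmentLabels) != 2L)
        return("treatmentLabels must have length 2")
    if (object@hubMaxNeighbors < 1)
        return("hubMaxNeighbors must be >= 1")
    TRUE
})
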