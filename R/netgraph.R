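#' Construct a MetabolicNetwork from an explicit edge list
#'
#' Low-level constructor: builds the network directly from
#' substrate/product pairs, merging parallel witnesses onto single
#' edges and dropping self-pairs. Used by [buildNetwork()] and useful
#' for assembling networks with known topology.
#'
#' @param edges data.frame with columns \code{substrate},
#'   \code{product}, and optionally \code{reaction_id}, \code{ec_id}
#'   witness columns (defaults supplied if absent).
#' @param scopeLabel one of \code{"meta"}, \code{"treatment_1"},
#'   \code{"treatment_2"}.
#' @param unmatchedEcs character, recorded unmatched query ECs.
#' @return a [MetabolicNetwork-class].
#' @export
metabolicNetwork <- function(edges, scopeLabel = "meta",
        unmatchedEcs = character(0)) {
    if (is.null(edges$reaction_id))
        edges$reaction_id <- rep("R_unspecified", nrow(edges))
    if (is.null(edges$ec_id)) edges$ec_id <- rep("-.-.-.-", nrow(edges))
    edges <- edges[edges$substrate != edges$product, , drop = FALSE]
    if (nrow(edges) == 0L) {
        ed <- data.frame(substrate = character(0), product = character(0),
            reactions = I(list()), ecs = I(list()),
            stringsAsFactors = FALSE)
        return(new("MetabolicNetwork", nodes = character(0), edges = ed,
            scopeLabel = scopeLabel, unmatchedEcs = unmatchedEcs))
    }
    key <- paste(edges$substrate, edges$product, sep = "\r")
    idx <- split(seq_len(nrow(edges)), factor(key, levels = unique(key)))
    ed <- data.frame(
        substrate = unname(vapply(idx, function(i) edges$substrate[i[1]],
            character(1))),
        product = unname(vapply(idx, function(i) edges$product[i[1]],
            character(1))),
        reactions = I(unname(lapply(idx,
            function(i) unique(edges$reaction_id[i])))),
        ecs = I(unname(lapply(idx, function(i) unique(edges$ec_id[i])))),
        stringsAsFactors = FALSE)
    rownames(ed) <- NULL
    new("MetabolicNetwork", nodes = unique(c(ed$substrate, ed$product)),
        edges = ed, scopeLabel = scopeLabel, unmatchedEcs = unmatchedEcs)
}

# expand a set of directed reactions into raw witness edges
# (substrate x product Cartesian pairs per reaction, one row per EC)
.reactionEdges <- function(rx) {
    if (nrow(rx) == 0L)
        return(data.frame(substrate = character(0), product = character(0),
            reaction_id = character(0), ec_id = character(0),
            stringsAsFactors = FALSE))
    parts <- lapply(seq_len(nrow(rx)), function(i) {
        g <- expand.grid(substrate = rx$substrates[[i]],
            product = rx$products[[i]], ec_id = rx$ec[[i]],
            stringsAsFactors = FALSE)
        g$reaction_id <- rx$reaction_id[[i]]
        g
    })
    do.call(rbind, parts)
}

#' Build a metabolite graph from a set of EC numbers
#'
#' Maps the query ECs to reactions ([ecToReactions()]) and projects
#' them onto a directed compound graph: every substrate of a reaction
#' is connected to every product (self-pairs skipped), and parallel
#' edges are merged with their (reaction, EC) witnesses. Called with
#' all ECs of the input table this yields the community meta-network;
#' called with a treatment's differential ECs it yields that
#' treatment's sub-network. If no reaction matches, an empty network is
#' returned with a warning.
#'
#' @param db a [ReactionDatabase-class].
#' @param ecs character vector of EC numbers.
#' @param scopeLabel scope recorded on the network.
#' @return a [MetabolicNetwork-class]; unmatched ECs are recorded in
#'   the object and retrievable via \code{object@unmatchedEcs}.
#' @export
buildNetwork <- function(db, ecs, scopeLabel = "meta") {
    rx <- ecToReactions(db, ecs)
    if (nrow(rx) == 0L) {
        warning(sprintf("no reaction matches the %d query EC(s); returning an empty %s network",
            length(ecs), scopeLabel), call. = FALSE)
    }
    metabolicNetwork(.reactionEdges(rx), scopeLabel,
        unmatchedEcs = attr(rx, "unmatched"))
}

#' Split a differential table into the three scope EC sets
#'
#' @param table a [DifferentialEnzymeTable-class].
#' @return list with character vectors \code{meta} (all ECs),
#'   \code{treatment_1} and \code{treatment_2} (the differential ECs of
#'   each treatment; disjoint by construction).
#' @export
scopeEcSets <- function(table) {
    rec <- table@records
    list(meta = rec$ec_id,
        treatment_1 = rec$ec_id[rec$association == "treatment_1"],
        treatment_2 = rec$ec_id[rec$association == "treatment_2"])
}

#' Export a network as edge-list and node-list TSV files
#'
#' @param net a [MetabolicNetwork-class].
#' @param edgePath,nodePath output TSV paths.
#' @return character(2) of the written paths, invisibly.
#' @export
exportNetwork <- function(net, edgePath, nodePath) {
    ed <- net@edges
    out <- data.frame(substrate = ed$substrate, product = ed$product,
        reaction_ids = vapply(ed$reactions, paste, character(1),
            collapse = ";"),
        ec_ids = vapply(ed$ecs, paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE)
    utils::write.table(out, edgePath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(
        data.frame(compound = sort(net@nodes), stringsAsFactors = FALSE),
        nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(edgePath, nodePath))
}

# igraph view of a MetabolicNetwork (nodes kept even if isolated
# after upstream filtering)
.asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        net@edges[, c("substrate", "product"), drop = FALSE],
        directed = TRUE, vertices = net@nodes)
}
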