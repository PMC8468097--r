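#' Strongly connected components of a metabolite graph
#'
#' Partitions the nodes into maximal sets of mutually reachable
#' compounds. The partition drives seed detection: contracting each
#' component yields an acyclic condensation whose source components
#' (no incoming edge from another component) hold the compounds the
#' network cannot produce internally.
#'
#' @param net a [MetabolicNetwork-class] (may be empty).
#' @return list with \code{membership} (named integer, node ->
#'   component id) and \code{components} (list of character vectors,
#'   indexed by component id).
#' @export
stronglyConnectedComponents <- function(net) {
    if (length(net@nodes) == 0L)
        return(list(membership = stats::setNames(integer(0), character(0)),
            components = list()))
    g <- .asIgraph(net)
    sc <- igraph::components(g, mode = "strong")
    membership <- stats::setNames(as.integer(sc$membership),
        names(sc$membership))
    list(membership = membership,
        components = split(names(membership), membership))
}

#' Predict environmental resource compounds (seed set) of a network
#'
#' Applies the reverse-ecology seed rule: compounds belonging to source
#' components of the SCC condensation -- components no other component
#' reaches -- cannot be produced by the network itself and are
#' predicted to be consumed from the environment. All members of a
#' multi-node source component are reported; component id and size are
#' kept as provenance so users can post-filter by component size.
#'
#' @param net a [MetabolicNetwork-class]; an empty network yields an
#'   empty proxy.
#' @return an [EnvironmentalProxy-class] with \code{filtered = FALSE}.
#' @export
detectSeeds <- function(net) {
    sc <- stronglyConnectedComponents(net)
    m <- sc$membership
    if (length(m) == 0L) {
        return(new("EnvironmentalProxy", compounds = character(0),
            provenance = data.frame(compound = character(0),
                scc_id = integer(0), scc_size = integer(0),
                stringsAsFactors = FALSE),
            scopeLabel = net@scopeLabel, filtered = FALSE))
    }
    ed <- net@edges
    csub <- m[ed$substrate]
    cprd <- m[ed$product]
    hasIncoming <- unique(cprd[csub != cprd])
    sourceIds <- setdiff(unique(m), hasIncoming)
    sizes <- table(m)
    seedNodes <- names(m)[m %in% sourceIds]
    prov <- data.frame(compound = seedNodes,
        scc_id = as.integer(m[seedNodes]),
        scc_size = as.integer(sizes[as.character(m[seedNodes])]),
        stringsAsFactors = FALSE)
    rownames(prov) <- NULL
    new("EnvironmentalProxy", compounds = seedNodes, provenance = prov,
        scopeLabel = net@scopeLabel, filtered = FALSE)
}

#' Intersect a treatment seed set with the meta-network seed set
#'
#' Treatment sub-networks are built from differential enzymes only and
#' are therefore highly fragmented, predicting artificial source
#' metabolites. Only compounds that are seeds of both the treatment
#' sub-network and the full meta-network are kept in the environment
#' proxy used for simulation.
#'
#' @param treatmentProxy unfiltered [EnvironmentalProxy-class] with a
#'   treatment scope.
#' @param metaProxy unfiltered [EnvironmentalProxy-class] with scope
#'   \code{"meta"}.
#' @return an [EnvironmentalProxy-class] with \code{filtered = TRUE};
#'   provenance rows are retained from the treatment proxy. A warning
#'   is issued when the intersection is empty.
#' @export
applyMetaFilter <- function(treatmentProxy, metaProxy) {
    if (treatmentProxy@scopeLabel == "meta")
        .stopf("contract error: treatment proxy has scope 'meta'")
    if (metaProxy@scopeLabel != "meta")
        .stopf("contract error: meta proxy has scope '%s'",
            metaProxy@scopeLabel)
    if (treatmentProxy@filtered || metaProxy@filtered)
        .stopf("contract error: inputs must be unfiltered proxies")
    keep <- intersect(treatmentProxy@compounds, metaProxy@compounds)
    if (length(keep) == 0L)
        warning(sprintf("empty environment proxy for %s after meta filtering",
            treatmentProxy@scopeLabel), call. = FALSE)
    prov <- treatmentProxy@provenance
    prov <- prov[prov$compound %in% keep, , drop = FALSE]
    rownames(prov) <- NULL
    new("EnvironmentalProxy", compounds = keep, provenance = prov,
        scopeLabel = treatmentProxy@scopeLabel, filtered = TRUE)
}

#' Write a resource list (one compound id per line)
#'
#' @param proxy an [EnvironmentalProxy-class].
#' @param path output text file.
#' @return \code{path}, invisibly.
#' @export
writeResourceList <- function(proxy, path) {
    writeLines(sort(proxy@compounds), path)
    invisible(path)
}
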