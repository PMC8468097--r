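#' Accessors for MetNetSim classes
#'
#' Small accessor generics exposing slots of the package's S4 classes;
#' user code should prefer these over direct slot access.
#'
#' @param object an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("treatmentLabels", function(object) standardGeneric("treatmentLabels"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("compoundNames", function(object) standardGeneric("compoundNames"))
#' @rdname accessors
#' @export
setGeneric("compoundPathways", function(object) standardGeneric("compoundPathways"))
#' @rdname accessors
#' @export
setGeneric("ecPathways", function(object) standardGeneric("ecPathways"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("scopeLabel", function(object) standardGeneric("scopeLabel"))
#' @rdname accessors
#' @export
setGeneric("seedCompounds", function(object) standardGeneric("seedCompounds"))
#' @rdname accessors
#' @export
setGeneric("seedProvenance", function(object) standardGeneric("seedProvenance"))
#' @rdname accessors
#' @export
setGeneric("isFiltered", function(object) standardGeneric("isFiltered"))
#' @rdname accessors
#' @export
setGeneric("producibleCompounds",
    function(object) standardGeneric("producibleCompounds"))
#' @rdname accessors
#' @export
setGeneric("firedReactions", function(object) standardGeneric("firedReactions"))
#' @rdname accessors
#' @export
setGeneric("expansionIterations",
    function(object) standardGeneric("expansionIterations"))

setMethod("records", "DifferentialEnzymeTable", function(object) object@records)
setMethod("treatmentLabels", "DifferentialEnzymeTable",
    function(object) object@treatmentLabels)
setMethod("reactions", "ReactionDatabase", function(object) object@reactions)
setMethod("compoundNames", "ReactionDatabase",
    function(object) object@compoundNames)
setMethod("compoundPathways", "ReactionDatabase",
    function(object) object@compoundPathways)
setMethod("ecPathways", "ReactionDatabase", function(object) object@ecPathways)
setMethod("networkNodes", "MetabolicNetwork", function(object) object@nodes)
setMethod("networkEdges", "MetabolicNetwork", function(object) object@edges)
setMethod("scopeLabel", "MetabolicNetwork", function(object) object@scopeLabel)
setMethod("scopeLabel", "EnvironmentalProxy", function(object) object@scopeLabel)
setMethod("scopeLabel", "ExpansionResult", function(object) object@scopeLabel)
setMethod("seedCompounds", "EnvironmentalProxy", function(object) object@compounds)
setMethod("seedCompounds", "ExpansionResult", function(object) object@seeds)
setMethod("seedProvenance", "EnvironmentalProxy",
    function(object) object@provenance)
setMethod("isFiltered", "EnvironmentalProxy", function(object) object@filtered)
setMethod("producibleCompounds", "ExpansionResult",
    function(object) object@producible)
setMethod("firedReactions", "ExpansionResult",
    function(object) object@firedReactions)
setMethod("expansionIterations", "ExpansionResult",
    function(object) object@iterations)

setMethod("show", "DifferentialEnzymeTable", function(object) {
    tab <- table(object@records$association)
    cat("DifferentialEnzymeTable with", nrow(object@records), "enzymes",
        sprintf("(%s vs %s)\n", object@treatmentLabels[1],
            object@treatmentLabels[2]))
    cat("  treatment_1:", tab[["treatment_1"]],
        " treatment_2:", tab[["treatment_2"]],
        " not_associated:", tab[["not_associated"]], "\n")
})

setMethod("show", "ReactionDatabase", function(object) {
    cat("ReactionDatabase:", nrow(object@reactions), "directed reactions",
        sprintf("(%d base reactions), %d compounds\n",
            length(unique(object@reactions$base_id)),
            length(object@compoundNames)))
    cat("  pathway annotations:", length(object@compoundPathways),
        "compounds,", length(object@ecPathways), "ECs\n")
})

setMethod("show", "MetabolicNetwork", function(object) {
    cat(sprintf("MetabolicNetwork [%s]: %d nodes, %d directed edges\n",
        object@scopeLabel, length(object@nodes), nrow(object@edges)))
    if (length(object@unmatchedEcs))
        cat("  unmatched ECs:", length(object@unmatchedEcs), "\n")
})

setMethod("show", "EnvironmentalProxy", function(object) {
    cat(sprintf("EnvironmentalProxy [%s%s]: %d compounds\n",
        object@scopeLabel, if (object@filtered) ", filtered" else "",
        length(object@compounds)))
})

setMethod("show", "ExpansionResult", function(object) {
    cat(sprintf(
        "ExpansionResult [%s]: %d seeds -> %d producible compounds, %d reactions fired in %d rounds\n",
        object@scopeLabel, length(object@seeds), length(object@producible),
        length(object@firedReactions), length(object@iterations)))
})
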