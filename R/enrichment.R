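#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: with the m p-values sorted ascending,
#' q(i) = min over j >= i of p(j) * m / j, capped at 1, and mapped back
#' to input order. Delegates to \code{stats::p.adjust(method = "BH")}
#' after validating the input range.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values in input order.
#' @export
bhFdr <- function(pValues) {
    if (length(pValues) == 0L) return(numeric(0))
    if (any(!is.finite(pValues) | pValues < 0 | pValues > 1))
        .stopf("contract error: p-values must lie in [0, 1]")
    stats::p.adjust(pValues, method = "BH")
}

#' Fisher-exact pathway over-representation test
#'
#' For every pathway, builds the 2x2 table of query membership vs
#' pathway membership within the universe and computes the one-sided
#' (over-representation) Fisher exact p-value, i.e. the hypergeometric
#' upper tail P(X >= k) with k = |query ∩ pathway|, K = |pathway ∩
#' universe|, n = |query|, N = |universe|. A pathway is tested iff
#' \code{minSize <= K <= maxSize}, it is not excluded, and \code{k >=
#' 1}; q-values are BH-adjusted over exactly the tested set, and a
#' pathway is flagged enriched when \code{q <= alpha}.
#'
#' @param entities character vector of query ids (ECs or compounds);
#'   must be a subset of \code{universe}.
#' @param universe character vector, the background pool the query was
#'   drawn from.
#' @param pathwayMap named list id -> character vector of pathway
#'   names (ids without annotation may be absent).
#' @param minSize,maxSize pathway size window, measured within the
#'   universe.
#' @param excluded pathway names excluded from testing (e.g. generic
#'   umbrella pathways).
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame with columns \code{pathway}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p_value}, \code{q_value},
#'   \code{enriched}, sorted by q, then p, then pathway name.
#' @export
fisherPathwayEnrichment <- function(entities, universe, pathwayMap,
        minSize = 1, maxSize = Inf, excluded = character(0),
        alpha = 0.05) {
    if (minSize > maxSize)
        .stopf("contract error: minSize must be <= maxSize")
    if (alpha <= 0 || alpha > 1)
        .stopf("contract error: alpha must be in (0, 1]")
    entities <- unique(as.character(entities))
    universe <- unique(as.character(universe))
    if (!all(entities %in% universe))
        .stopf("contract error: query entities outside the universe: %s",
            paste(utils::head(setdiff(entities, universe), 5), collapse = ", "))
    N <- length(universe)
    n <- length(entities)
    annotated <- pathwayMap[names(pathwayMap) %in% universe]
    pw <- unique(unlist(annotated))
    rows <- lapply(pw, function(p) {
        members <- names(annotated)[vapply(annotated,
            function(x) p %in% x, logical(1))]
        K <- length(members)
        k <- length(intersect(members, entities))
        if (K < minSize || K > maxSize || p %in% excluded || k < 1L)
            return(NULL)
        data.frame(pathway = p, k = k, K = K, n = n, N = N,
            p_value = stats::phyper(k - 1L, K, N - K, n,
                lower.tail = FALSE),
            stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
        return(data.frame(pathway = character(0), k = integer(0),
            K = integer(0), n = integer(0), N = integer(0),
            p_value = numeric(0), q_value = numeric(0),
            enriched = logical(0), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out$q_value <- bhFdr(out$p_value)
    out$enriched <- out$q_value <= alpha
    out <- out[order(out$q_value, out$p_value, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Entity-to-pathway mapping table for export
#'
#' One row per (entity, pathway) pair; entities carrying no pathway
#' annotation are emitted once with the pathway marker
#' \code{"unannotated"}.
#'
#' @param entities character vector of ids.
#' @param pathwayMap named list id -> pathway names.
#' @return data.frame with columns \code{entity}, \code{pathway}.
#' @export
pathwayTable <- function(entities, pathwayMap) {
    entities <- unique(as.character(entities))
    rows <- lapply(entities, function(e) {
        p <- pathwayMap[[e]]
        if (is.null(p) || length(p) == 0L) p <- "unannotated"
        data.frame(entity = e, pathway = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows) %||%
        data.frame(entity = character(0), pathway = character(0),
            stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
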