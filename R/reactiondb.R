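# The flat-file dialect (pipe-delimited, one record per line, "#" comments):
#   reactions.tsv:          reaction_id | EC;EC;... | substrate;... | product;... | forward|reversible
#   compounds.tsv:          compound_id | display name
#   pathways_compounds.tsv: compound_id | pathway name
#   pathways_ecs.tsv:       ec | pathway name

.readPipeFile <- function(path, nfields) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (!length(lines)) return(NULL)
    parts <- strsplit(lines, "|", fixed = TRUE)
    bad <- lengths(parts) != nfields
    if (any(bad))
        .stopf("format error in %s: expected %d pipe-delimited fields, line(s): %s",
            path, nfields, paste(which(bad), collapse = ", "))
    m <- t(vapply(parts, function(p) trimws(p), character(nfields)))
    matrix(m, ncol = nfields)
}

# materialize directed reactions: a reversible base reaction becomes two
# entries "<id>_f" and "<id>_r" with substrate/product roles swapped
.splitDirections <- function(base) {
    n <- nrow(base)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        if (base$reversible[[i]]) {
            rows[[i]] <- data.frame(
                reaction_id = paste0(base$base_id[[i]], c("_f", "_r")),
                base_id = base$base_id[[i]],
                ec = I(list(base$ec[[i]], base$ec[[i]])),
                substrates = I(list(base$substrates[[i]], base$products[[i]])),
                products = I(list(base$products[[i]], base$substrates[[i]])),
                reversible = TRUE, stringsAsFactors = FALSE)
        } else {
            rows[[i]] <- data.frame(
                reaction_id = base$base_id[[i]], base_id = base$base_id[[i]],
                ec = I(base$ec[i]), substrates = I(base$substrates[i]),
                products = I(base$products[i]), reversible = FALSE,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Construct a ReactionDatabase from base (undirected) reaction records
#'
#' @param baseReactions data.frame with columns \code{base_id},
#'   list-columns \code{ec}, \code{substrates}, \code{products}, and
#'   logical \code{reversible}. Reversible reactions are split into two
#'   directed entries (\code{_f}/\code{_r} suffixes).
#' @param compoundNames named character compound id -> display name.
#' @param compoundPathways named list compound id -> pathway names.
#' @param ecPathways named list EC -> pathway names.
#' @param allowSelfConversion permit substrate/product overlap.
#' @return a [ReactionDatabase-class].
#' @export
reactionDatabase <- function(baseReactions, compoundNames,
        compoundPathways = list(), ecPathways = list(),
        allowSelfConversion = FALSE) {
    if (anyDuplicated(baseReactions$base_id))
        .stopf("duplicated reaction id(s): %s", paste(
            unique(baseReactions$base_id[duplicated(baseReactions$base_id)]),
            collapse = ", "))
    # pathway maps are stored sorted by id so that write/load round-trips
    # are exact regardless of input order
    if (length(compoundPathways))
        compoundPathways <- compoundPathways[order(names(compoundPathways))]
    if (length(ecPathways))
        ecPathways <- ecPathways[order(names(ecPathways))]
    new("ReactionDatabase", reactions = .splitDirections(baseReactions),
        compoundNames = compoundNames, compoundPathways = compoundPathways,
        ecPathways = ecPathways, allowSelfConversion = allowSelfConversion)
}

#' Load a reaction database from the flat-file dialect
#'
#' Reads the pipe-delimited database files: required \code{reactions}
#' and \code{compounds}, optional \code{compound_pathways} and
#' \code{ec_pathways}. Reactions marked \code{reversible} are
#' materialized as two directed reactions with \code{_f}/\code{_r}
#' suffixes; direction labels \code{forward} and \code{irreversible}
#' are synonymous. Validation errors (duplicate reaction ids, empty
#' substrate or product lists, compounds referenced but not declared)
#' abort with a message naming the offender.
#'
#' @param paths named character (or list) with elements
#'   \code{reactions}, \code{compounds}, and optionally
#'   \code{compound_pathways}, \code{ec_pathways}.
#' @param allowSelfConversion permit a compound to appear as both
#'   substrate and product of one reaction (default FALSE).
#' @return a [ReactionDatabase-class].
#' @examples
#' d <- system.file("extdata", "example", package = "MetNetSim")
#' db <- loadReactionDatabase(c(
#'     reactions = file.path(d, "reactions.tsv"),
#'     compounds = file.path(d, "compounds.tsv"),
#'     compound_pathways = file.path(d, "pathways_compounds.tsv"),
#'     ec_pathways = file.path(d, "pathways_ecs.tsv")))
#' db
#' @export
loadReactionDatabase <- function(paths, allowSelfConversion = FALSE) {
    paths <- unlist(paths)
    for (k in c("reactions", "compounds"))
        if (!k %in% names(paths))
            .stopf("database paths must include '%s'", k)
    cm <- .readPipeFile(paths[["compounds"]], 2L)
    if (is.null(cm)) .stopf("compound file %s has no records",
        paths[["compounds"]])
    compoundNames <- stats::setNames(cm[, 2], cm[, 1])
    rm <- .readPipeFile(paths[["reactions"]], 5L)
    if (is.null(rm)) .stopf("reaction file %s has no records",
        paths[["reactions"]])
    dirlab <- tolower(rm[, 5])
    ok <- dirlab %in% c("forward", "irreversible", "reversible")
    if (!all(ok))
        .stopf("unknown direction label(s): %s",
            paste(unique(rm[!ok, 5]), collapse = ", "))
    base <- data.frame(base_id = rm[, 1],
        ec = I(lapply(rm[, 2], .splitField)),
        substrates = I(lapply(rm[, 3], .splitField)),
        products = I(lapply(rm[, 4], .splitField)),
        reversible = dirlab == "reversible", stringsAsFactors = FALSE)
    empty <- lengths(base$substrates) == 0L | lengths(base$products) == 0L
    if (any(empty))
        .stopf("empty substrate or product list in reaction(s): %s",
            paste(base$base_id[empty], collapse = ", "))
    referenced <- unique(c(unlist(base$substrates), unlist(base$products)))
    dangling <- setdiff(referenced, names(compoundNames))
    if (length(dangling))
        .stopf("reaction file references undeclared compound(s): %s",
            paste(dangling, collapse = ", "))
    cpw <- list()
    if ("compound_pathways" %in% names(paths)) {
        pm <- .readPipeFile(paths[["compound_pathways"]], 2L)
        if (!is.null(pm))
            cpw <- lapply(split(pm[, 2], pm[, 1]), unique)
    }
    epw <- list()
    if ("ec_pathways" %in% names(paths)) {
        pm <- .readPipeFile(paths[["ec_pathways"]], 2L)
        if (!is.null(pm))
            epw <- lapply(split(pm[, 2], pm[, 1]), unique)
    }
    reactionDatabase(base, compoundNames, cpw, epw, allowSelfConversion)
}

#' Write a reaction database in the flat-file dialect
#'
#' Inverse of [loadReactionDatabase()]: the split directed reactions are
#' re-merged into base records (reversible reactions written once), so
#' \code{loadReactionDatabase(writeReactionDatabase(db, dir))}
#' reproduces \code{db}.
#'
#' @param db a [ReactionDatabase-class].
#' @param dir output directory (created if needed).
#' @return named character of the written file paths, invisibly.
#' @export
writeReactionDatabase <- function(db, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rx <- db@reactions
    keep <- !rx$reversible | grepl("_f$", rx$reaction_id)
    bs <- rx[keep, , drop = FALSE]
    lines <- vapply(seq_len(nrow(bs)), function(i) {
        paste(bs$base_id[[i]], paste(bs$ec[[i]], collapse = ";"),
            paste(bs$substrates[[i]], collapse = ";"),
            paste(bs$products[[i]], collapse = ";"),
            if (bs$reversible[[i]]) "reversible" else "forward",
            sep = " | ")
    }, character(1))
    paths <- c(reactions = file.path(dir, "reactions.tsv"),
        compounds = file.path(dir, "compounds.tsv"),
        compound_pathways = file.path(dir, "pathways_compounds.tsv"),
        ec_pathways = file.path(dir, "pathways_ecs.tsv"))
    writeLines(lines, paths[["reactions"]])
    writeLines(paste(names(db@compoundNames), db@compoundNames, sep = " | "),
        paths[["compounds"]])
    cpw <- db@compoundPathways
    writeLines(unlist(lapply(names(cpw), function(id)
        paste(id, cpw[[id]], sep = " | "))) %||% character(0),
        paths[["compound_pathways"]])
    epw <- db@ecPathways
    writeLines(unlist(lapply(names(epw), function(id)
        paste(id, epw[[id]], sep = " | "))) %||% character(0),
        paths[["ec_pathways"]])
    invisible(paths)
}

#' Map a set of EC numbers to the reactions they catalyze
#'
#' Returns every directed reaction whose EC annotation intersects the
#' query set. Matching is exact: a partial EC such as \code{"1.1.1.-"}
#' matches only reactions annotated with that identifier. Query ECs
#' with no reaction in the database are reported in the
#' \code{"unmatched"} attribute, not treated as an error.
#'
#' @param db a [ReactionDatabase-class].
#' @param ecs character vector of EC numbers.
#' @return the matching rows of \code{reactions(db)}, with attribute
#'   \code{unmatched}: the query ECs hitting no reaction.
#' @export
ecToReactions <- function(db, ecs) {
    rx <- db@reactions
    hit <- vapply(rx$ec, function(e) any(e %in% ecs), logical(1))
    out <- rx[hit, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "unmatched") <- setdiff(ecs, unique(unlist(rx$ec)))
    out
}
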