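#' Construct a DifferentialEnzymeTable from a data.frame
#'
#' Low-level constructor used by [parseDifferentialTable()] and by code
#' that builds tables programmatically (e.g. fixture generation).
#'
#' @param records data.frame with columns \code{ec_id}, \code{log_fc},
#'   \code{p_value}, \code{adj_p_value}, \code{association}; association
#'   values must already be canonical (\code{treatment_1},
#'   \code{treatment_2}, \code{not_associated}).
#' @param treatmentLabels character(2) display names for the two
#'   treatments.
#' @return a [DifferentialEnzymeTable-class] object.
#' @export
differentialTable <- function(records,
        treatmentLabels = c("treatment_1", "treatment_2")) {
    records$ec_id <- as.character(records$ec_id)
    records$association <- factor(as.character(records$association),
        levels = .ASSOCIATION_LEVELS)
    rownames(records) <- NULL
    new("DifferentialEnzymeTable", records = records,
        treatmentLabels = as.character(treatmentLabels))
}

# sniff the delimiter from the header line: the candidate producing the
# most fields wins
.sniffDelimiter <- function(line, candidates = c(",", "\t", ";")) {
    counts <- vapply(candidates,
        function(s) length(strsplit(line, s, fixed = TRUE)[[1]]), integer(1))
    candidates[which.max(counts)]
}

#' Default column-name dialect of differential-abundance files
#'
#' Upstream differential-abundance tools label their output columns
#' inconsistently across versions; the parser therefore takes a dialect
#' of expected column names, with edgeR-style defaults.
#'
#' @param ec,log_fc,p_value,adj_p_value,association column names in the
#'   input file holding the respective fields.
#' @return named list of column names.
#' @export
tableDialect <- function(ec = "ec", log_fc = "logFC", p_value = "PValue",
        adj_p_value = "FDR", association = "association") {
    list(ec = ec, log_fc = log_fc, p_value = p_value,
        adj_p_value = adj_p_value, association = association)
}

# map free-form association labels (case-insensitive, synonyms, user
# display names) onto the canonical three-level factor
.mapAssociation <- function(x, treatmentLabels) {
    syn <- c(
        structure(rep("treatment_1", 3), names = .normLabel(
            c("treatment_1", "t1", treatmentLabels[1]))),
        structure(rep("treatment_2", 3), names = .normLabel(
            c("treatment_2", "t2", treatmentLabels[2]))),
        structure(rep("not_associated", 4), names = .normLabel(
            c("not_associated", "notassoc", "none", "ns"))))
    key <- .normLabel(x)
    out <- unname(syn[key])
    if (anyNA(out)) {
        bad <- unique(x[is.na(out)])
        .stopf("unmappable association label(s): %s",
            paste(bad, collapse = ", "))
    }
    out
}

#' Parse a differential enzyme abundance file
#'
#' Reads the single user input file: a delimited table with one EC
#' number per row, its log2 fold change, raw and adjusted p-values, and
#' a three-way association label (treatment 1 / treatment 2 / not
#' associated) as produced by an edgeR-style differential abundance
#' analysis of annotated metagenomic reads. The delimiter is
#' auto-detected among comma, tab and semicolon; a leading \code{"ec:"}
#' prefix on EC identifiers is stripped; association labels are matched
#' case-insensitively against canonical names, common synonyms and the
#' supplied treatment display names.
#'
#' @param path path to the delimited text file (UTF-8, header row
#'   required).
#' @param dialect column-name mapping, see [tableDialect()].
#' @param treatmentLabels character(2) display names; rows labelled with
#'   these names are mapped to \code{treatment_1} / \code{treatment_2}.
#' @return a [DifferentialEnzymeTable-class]; rows keep file order.
#' @examples
#' f <- system.file("extdata", "example", "differential_enzymes.csv",
#'     package = "MetNetSim")
#' tab <- parseDifferentialTable(f, treatmentLabels = c("root", "soil"))
#' tab
#' @export
parseDifferentialTable <- function(path, dialect = tableDialect(),
        treatmentLabels = c("treatment_1", "treatment_2")) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        .stopf("format error: file %s is empty", path)
    sep <- .sniffDelimiter(lines[[1]])
    df <- utils::read.table(text = lines, header = TRUE, sep = sep,
        quote = "\"", stringsAsFactors = FALSE, strip.white = TRUE,
        check.names = FALSE, comment.char = "")
    missing <- setdiff(unlist(dialect), names(df))
    if (length(missing))
        .stopf("format error: missing required column(s): %s",
            paste(missing, collapse = ", "))
    if (nrow(df) == 0L)
        .stopf("validation error: empty data section")
    ec <- trimws(as.character(df[[dialect$ec]]))
    ec <- sub("^ec:", "", ec, ignore.case = TRUE)
    bad <- ec[!grepl(.EC_PATTERN, ec)]
    if (length(bad))
        .stopf("validation error: malformed EC id(s): %s",
            paste(unique(bad), collapse = ", "))
    if (anyDuplicated(ec))
        .stopf("validation error: duplicate EC id(s): %s",
            paste(unique(ec[duplicated(ec)]), collapse = ", "))
    rec <- data.frame(
        ec_id = ec,
        log_fc = as.numeric(df[[dialect$log_fc]]),
        p_value = as.numeric(df[[dialect$p_value]]),
        adj_p_value = as.numeric(df[[dialect$adj_p_value]]),
        association = .mapAssociation(
            as.character(df[[dialect$association]]), treatmentLabels),
        stringsAsFactors = FALSE)
    differentialTable(rec, treatmentLabels)
}

#' Write a DifferentialEnzymeTable back to the input dialect
#'
#' Inverse of [parseDifferentialTable()]: re-parsing the written file
#' yields an identical table.
#'
#' @param table a [DifferentialEnzymeTable-class].
#' @param path output file path.
#' @param dialect column-name mapping, see [tableDialect()].
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeDifferentialTable <- function(table, path, dialect = tableDialect(),
        sep = ",") {
    rec <- table@records
    out <- data.frame(rec$ec_id, rec$log_fc, rec$p_value, rec$adj_p_value,
        as.character(rec$association), stringsAsFactors = FALSE)
    names(out) <- unlist(dialect)
    utils::write.table(out, path, sep = sep, quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Summarize the composition of a differential enzyme table
#'
#' Computes per-association counts and fractions plus the vectors needed
#' for the standard three diagnostic panels (volcano-style scatter of
#' adjusted p-value vs logFC, association pie, p-value histogram).
#'
#' @param table a [DifferentialEnzymeTable-class].
#' @return list with elements \code{counts} (named integer),
#'   \code{fractions} (named numeric summing to 1), \code{total}, and
#'   \code{points}: data.frame of (\code{log_fc}, \code{adj_p_value},
#'   \code{p_value}, \code{association}) per enzyme.
#' @export
summarizeTable <- function(table) {
    rec <- table@records
    counts <- table(rec$association)
    counts <- stats::setNames(as.integer(counts), names(counts))
    list(counts = counts,
        fractions = counts / sum(counts),
        total = nrow(rec),
        points = data.frame(log_fc = rec$log_fc,
            adj_p_value = rec$adj_p_value, p_value = rec$p_value,
            association = as.character(rec$association),
            stringsAsFactors = FALSE))
}

#' Export a table summary as JSON
#'
#' @param summary output of [summarizeTable()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSummaryJson <- function(summary, path) {
    jsonlite::write_json(
        list(counts = as.list(summary$counts),
            fractions = as.list(summary$fractions),
            total = summary$total),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Plot the three input-composition panels
#'
#' Draws a scatter of adjusted p-value (-log10) versus logFC, a pie
#' chart of the association fractions, and a p-value histogram, colored
#' by association class.
#'
#' @param summary output of [summarizeTable()].
#' @param path PNG output path.
#' @param palette named colors for the three association classes.
#' @return \code{path}, invisibly.
#' @export
plotSummary <- function(summary, path,
        palette = c(treatment_1 = "#d95f02", treatment_2 = "#1b9e77",
            not_associated = "grey60")) {
    pts <- summary$points
    grDevices::png(path, width = 1500, height = 500, res = 110)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    graphics::plot(pts$log_fc, -log10(pmax(pts$adj_p_value, 1e-300)),
        col = palette[pts$association], pch = 19, cex = 0.6,
        xlab = "logFC", ylab = "-log10 adjusted p-value",
        main = "Differential abundance")
    graphics::pie(summary$counts, col = palette[names(summary$counts)],
        main = "Association classes")
    graphics::hist(pts$p_value, breaks = 20, col = "grey80",
        xlab = "p-value", main = "p-value distribution")
    invisible(path)
}
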