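# dotted EC pattern; partial ECs such as "1.1.1.-" are legal
.EC_PATTERN <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a ;-separated field into a trimmed character vector, dropping blanks
.splitField <- function(x, sep = ";") {
    v <- trimws(strsplit(x, sep, fixed = TRUE)[[1]])
    v[nzchar(v)]
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# normalize association labels for synonym matching: lowercase, strip
# separators ("Treatment_1", "treatment1", "T 1" all collapse to same key)
.normLabel <- function(x) gsub("[ _.-]", "", tolower(x))

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# stable number formatting for byte-reproducible text exports
.fmtNum <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
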