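#' Network expansion: closure of producible compounds from a seed set
#'
#' Implements the network-expansion fixed point: starting from the seed
#' compounds, every reaction whose complete substrate set is available
#' fires and adds its products to the pool; rounds repeat until no new
#' reaction fires. Chemistry is set-based -- once produced, a compound
#' remains available -- so the result is the unique least fixed point
#' and is independent of the order reactions are listed in.
#'
#' @param reactionBank data.frame of directed reactions (rows of
#'   \code{reactions(db)}, e.g. from [ecToReactions()]).
#' @param seeds character vector of seed compound ids (may be empty).
#' @param scopeLabel scope recorded on the result.
#' @return an [ExpansionResult-class] with the producible closure, the
#'   fired reactions, and the per-round layers of newly fired reactions
#'   and newly produced compounds.
#' @examples
#' fx <- generateFixtureDatabase(20, 25, randomSeed = 7)
#' res <- expandNetwork(reactions(fx$db), fx$seeds)
#' setequal(producibleCompounds(res), fx$closure)
#' @export
expandNetwork <- function(reactionBank, seeds, scopeLabel = "meta") {
    seeds <- unique(as.character(seeds))
    nR <- nrow(reactionBank)
    pool <- seeds
    fired <- logical(nR)
    iterations <- list()
    if (nR > 0L) {
        # unmet[i]: number of distinct substrates of reaction i not yet
        # in the pool; a reaction fires when unmet drops to zero
        subsList <- lapply(reactionBank$substrates, unique)
        unmet <- lengths(subsList)
        cpdToRx <- split(rep(seq_len(nR), lengths(subsList)),
            unlist(subsList))
        avail <- seeds
        repeat {
            for (c in avail[avail %in% names(cpdToRx)])
                unmet[cpdToRx[[c]]] <- unmet[cpdToRx[[c]]] - 1L
            ready <- which(!fired & unmet == 0L)
            if (length(ready) == 0L) break
            fired[ready] <- TRUE
            newProducts <- setdiff(
                unique(unlist(reactionBank$products[ready])), pool)
            iterations[[length(iterations) + 1L]] <- list(
                reactions = reactionBank$reaction_id[ready],
                compounds = newProducts)
            pool <- c(pool, newProducts)
            avail <- newProducts
            if (length(newProducts) == 0L) break
        }
    }
    new("ExpansionResult", seeds = seeds, producible = pool,
        firedReactions = if (nR) reactionBank$reaction_id[fired]
            else character(0),
        iterations = iterations, scopeLabel = scopeLabel)
}

#' Simulate metabolic activity of both treatments over the meta bank
#'
#' Runs the network expansion twice over the identical reaction bank --
#' all reactions reachable from the full (meta) EC set, differential
#' and non-differential alike -- seeding each run with a
#' treatment-specific environment proxy. Differences between the two
#' closures therefore reflect only the predicted environmental
#' resources, not the reaction repertoire.
#'
#' @param db a [ReactionDatabase-class].
#' @param metaEcs character vector, all ECs of the input table.
#' @param proxy1,proxy2 filtered [EnvironmentalProxy-class] objects for
#'   treatment 1 and treatment 2.
#' @param auxiliarySeedCompounds compounds added to both seed sets
#'   (default empty: the proxies alone seed the expansion).
#' @return list of two [ExpansionResult-class] objects named
#'   \code{treatment_1}, \code{treatment_2}.
#' @export
simulateTreatments <- function(db, metaEcs, proxy1, proxy2,
        auxiliarySeedCompounds = character(0)) {
    if (!proxy1@filtered || !proxy2@filtered)
        .stopf("contract error: proxies must be meta-filtered (filtered=TRUE)")
    bank <- ecToReactions(db, metaEcs)
    list(
        treatment_1 = expandNetwork(bank,
            c(proxy1@compounds, auxiliarySeedCompounds), proxy1@scopeLabel),
        treatment_2 = expandNetwork(bank,
            c(proxy2@compounds, auxiliarySeedCompounds), proxy2@scopeLabel))
}

#' Compounds unique to each treatment's expansion
#'
#' @param result1,result2 [ExpansionResult-class] objects from the same
#'   reaction bank.
#' @return list of two disjoint character vectors named
#'   \code{treatment_1} (producible in 1 but not 2) and
#'   \code{treatment_2} (producible in 2 but not 1).
#' @export
uniqueCompounds <- function(result1, result2) {
    list(treatment_1 = setdiff(result1@producible, result2@producible),
        treatment_2 = setdiff(result2@producible, result1@producible))
}

#' Write a compound list (one compound id per line)
#'
#' @param compounds character vector of compound ids.
#' @param path output text file.
#' @return \code{path}, invisibly.
#' @export
writeCompoundList <- function(compounds, path) {
    writeLines(sort(compounds), path)
    invisible(path)
}
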