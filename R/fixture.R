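# Synthetic reaction-database generator with planted ground truth.
#
# Construction guarantees, by induction over a fixed compound order:
#   * the k designated source compounds are never produced by any
#     reaction, each is consumed at least once, and every strongly
#     connected component containing more than one node (or any
#     non-source node) has an incoming edge from outside it -- so the
#     source components of the compound graph are exactly the k
#     singleton sources;
#   * every non-source compound is the product of a reaction whose
#     substrates are earlier in the order, so the expansion closure
#     from the sources is the full compound set and every directed
#     reaction fires.
# Extra reactions beyond the producing skeleton are either back-edges
# (a descendant feeds an ancestor, creating a cycle whose earliest node
# keeps an external parent) or reversible lateral conversions between
# two non-adjacent non-source compounds.

#' Generate a synthetic reaction database with known seeds and closure
#'
#' Builds a deterministic random database emulating the KEGG-like
#' scheme: a producing DAG skeleton rooted in a set of source
#' compounds, plus optional cycles and reversible lateral reactions,
#' with compounds and ECs randomly annotated to pathways. The true
#' environmental seed set (the planted sources) and the true expansion
#' closure from those sources are returned alongside the database, so
#' topology-based predictions can be checked against construction-time
#' ground truth.
#'
#' @param nCompounds number of compounds (>= 2).
#' @param nReactions number of base reactions; must be at least
#'   \code{nCompounds - k} (one producing reaction per non-source
#'   compound, where k is the number of planted sources) and no more
#'   than the number of orderable compound pairs permits.
#' @param fractionReversible fraction of the extra (non-skeleton)
#'   reactions realized as reversible lateral conversions; the rest
#'   become irreversible cycle-closing back-edges.
#' @param nPathways number of pathway labels to scatter over compounds
#'   and ECs.
#' @param randomSeed integer seed; output is byte-identical for equal
#'   seeds.
#' @param sourceFraction fraction of compounds planted as sources
#'   (default 0.15, at least 1, at most half the compounds).
#' @return list with elements \code{db} ([ReactionDatabase-class]),
#'   \code{seeds} (planted source compounds), \code{closure} (true
#'   producible set from the seeds; here all compounds) and
#'   \code{sourceComponents} (list of singleton components, one per
#'   seed).
#' @export
generateFixtureDatabase <- function(nCompounds, nReactions,
        fractionReversible = 0.25, nPathways = 5, randomSeed = 1,
        sourceFraction = 0.15) {
    stopifnot(nCompounds >= 2, nReactions >= 1, nPathways >= 1,
        fractionReversible >= 0, fractionReversible <= 1)
    .withSeed(randomSeed, {
        k <- max(1L, min(as.integer(floor(nCompounds / 2)),
            as.integer(round(sourceFraction * nCompounds))))
        nProd <- nCompounds - k
        if (nReactions < nProd)
            .stopf("infeasible spec: %d reactions cannot produce %d non-source compounds",
                nReactions, nProd)
        cpd <- sprintf("C%05d", seq_len(nCompounds))
        sources <- cpd[seq_len(k)]
        produced <- cpd[(k + 1L):nCompounds]
        parent <- character(0)       # designated parent per produced compound
        subs <- vector("list", 0)
        prods <- vector("list", 0)
        revs <- logical(0)
        # producing skeleton: compound i gets 1-2 substrates from earlier
        # compounds; the first k produced compounds each consume one source
        # so every source appears in the graph
        for (i in seq_len(nProd)) {
            avail <- c(sources, produced[seq_len(i - 1L)])
            first <- if (i <= k) sources[i] else sample(avail, 1L)
            ns <- if (length(avail) > 1L && stats::runif(1) < 0.35) 2L else 1L
            s <- unique(c(first,
                if (ns == 2L) sample(setdiff(avail, first), 1L)))
            parent[produced[i]] <- first
            subs[[length(subs) + 1L]] <- s
            prods[[length(prods) + 1L]] <- produced[i]
            revs <- c(revs, FALSE)
        }
        nExtra <- nReactions - nProd
        if (nExtra > 0L) {
            ancestors <- function(x) {
                out <- character(0)
                while (x %in% names(parent) && parent[[x]] %in% produced) {
                    x <- parent[[x]]
                    out <- c(out, x)
                }
                out
            }
            nRev <- as.integer(round(fractionReversible * nExtra))
            used <- character(0)   # avoid duplicate extra reactions
            placeExtra <- function(reversible) {
                for (try in seq_len(400L)) {
                    if (!reversible) {
                        # an irreversible extra: either a cycle-closing
                        # back-edge b -> a (a a produced ancestor of b) or
                        # a forward shortcut u -> v with u earlier than v
                        b <- sample(produced, 1L)
                        anc <- ancestors(b)
                        if (length(anc) && try %% 2L == 1L) {
                            a <- sample(anc, 1L)
                            key <- paste("x", b, a)
                            if (key %in% used) next
                            subs[[length(subs) + 1L]] <<- b
                            prods[[length(prods) + 1L]] <<- a
                        } else {
                            iv <- match(b, produced)
                            earlier <- c(sources, produced[seq_len(iv - 1L)])
                            earlier <- setdiff(earlier, b)
                            if (!length(earlier)) next
                            u <- sample(earlier, 1L)
                            key <- paste("x", u, b)
                            if (key %in% used) next
                            subs[[length(subs) + 1L]] <<- u
                            prods[[length(prods) + 1L]] <<- b
                        }
                        revs <<- c(revs, FALSE)
                    } else {
                        # reversible lateral x <-> y, both non-source,
                        # neither a substrate of the other's producing
                        # reaction (keeps an external parent outside {x,y})
                        if (length(produced) < 2L) break
                        xy <- sample(produced, 2L)
                        x <- xy[1]; y <- xy[2]
                        ix <- match(x, produced); iy <- match(y, produced)
                        if (y %in% subs[[ix]] || x %in% subs[[iy]]) next
                        key <- paste("lat", paste(sort(xy), collapse = "~"))
                        if (key %in% used) next
                        subs[[length(subs) + 1L]] <<- x
                        prods[[length(prods) + 1L]] <<- y
                        revs <<- c(revs, TRUE)
                    }
                    used <<- c(used, key)
                    return(TRUE)
                }
                FALSE
            }
            for (j in seq_len(nExtra)) {
                wantRev <- j > nExtra - nRev
                # when the reversible lateral pairs are exhausted, fall
                # back to an irreversible extra so fractionReversible
                # acts as an upper bound
                made <- placeExtra(wantRev) ||
                    (wantRev && placeExtra(FALSE))
                if (!made)
                    .stopf("infeasible spec: cannot place %d extra reactions among orderable pairs",
                        nExtra)
            }
        }
        n <- length(subs)
        ecs <- sprintf("%d.%d.%d.%d",
            sample(1:6, n, replace = TRUE), sample(1:20, n, replace = TRUE),
            sample(1:20, n, replace = TRUE), seq_len(n))
        base <- data.frame(base_id = sprintf("R%05d", seq_len(n)),
            ec = I(as.list(ecs)), substrates = I(subs), products = I(prods),
            reversible = revs, stringsAsFactors = FALSE)
        pathways <- sprintf("Pathway_%02d", seq_len(nPathways))
        cpw <- lapply(stats::setNames(cpd, cpd), function(x) {
            np <- sample(0:2, 1L)
            if (np == 0L) NULL else sort(sample(pathways, np))
        })
        cpw <- cpw[!vapply(cpw, is.null, logical(1))]
        epw <- lapply(stats::setNames(ecs, ecs), function(x) {
            np <- sample(0:2, 1L)
            if (np == 0L) NULL else sort(sample(pathways, np))
        })
        epw <- epw[!vapply(epw, is.null, logical(1))]
        db <- reactionDatabase(base,
            compoundNames = stats::setNames(paste("compound", cpd), cpd),
            compoundPathways = cpw, ecPathways = epw)
        list(db = db, seeds = sources, closure = cpd,
            sourceComponents = as.list(sources))
    })
}

#' Generate a differential enzyme table matching a fixture database
#'
#' Assigns every EC of the database to one of the three association
#' classes at the given proportions and draws log fold changes and
#' p-values consistent with the class (differential enzymes get large
#' |logFC| and small adjusted p-values), yielding a valid upstream
#' input table for pipeline runs on synthetic data.
#'
#' @param db a [ReactionDatabase-class] (typically from
#'   [generateFixtureDatabase()]).
#' @param proportions numeric(3) mixing proportions for treatment_1,
#'   treatment_2, not_associated (normalized internally).
#' @param randomSeed integer seed.
#' @param treatmentLabels display names for the two treatments.
#' @return a [DifferentialEnzymeTable-class] covering every EC in the
#'   database.
#' @export
generateFixtureTable <- function(db, proportions = c(0.3, 0.3, 0.4),
        randomSeed = 1, treatmentLabels = c("treatment_1", "treatment_2")) {
    .withSeed(randomSeed, {
        ecs <- sort(unique(unlist(db@reactions$ec)))
        pr <- proportions / sum(proportions)
        assoc <- sample(.ASSOCIATION_LEVELS, length(ecs), replace = TRUE,
            prob = pr)
        diffrow <- assoc != "not_associated"
        lfc <- stats::rnorm(length(ecs), 0, 0.3)
        lfc[diffrow] <- (2 + abs(stats::rnorm(sum(diffrow), 1, 1))) *
            ifelse(assoc[diffrow] == "treatment_1", 1, -1)
        p <- stats::runif(length(ecs), 0.05, 1)
        p[diffrow] <- stats::runif(sum(diffrow), 1e-8, 0.01)
        adj <- pmin(1, p * 1.5)
        differentialTable(data.frame(ec_id = ecs, log_fc = lfc,
            p_value = p, adj_p_value = adj, association = assoc,
            stringsAsFactors = FALSE), treatmentLabels)
    })
}
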