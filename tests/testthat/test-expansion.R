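miniBank <- function() {
    data.frame(reaction_id = c("R1", "R2"), base_id = c("R1", "R2"),
        ec = I(list("1.1.1.1", "1.1.1.2")),
        substrates = I(list("C1", c("C2", "C5"))),
        products = I(list("C2", "C3")),
        reversible = FALSE, stringsAsFactors = FALSE)
}

test_that("a reaction fires only when its full substrate set is present", {
    res <- expandNetwork(miniBank(), "C1")
    expect_setequal(producibleCompounds(res), c("C1", "C2"))
    expect_equal(firedReactions(res), "R1")
    res2 <- expandNetwork(miniBank(), c("C1", "C5"))
    expect_setequal(producibleCompounds(res2), c("C1", "C2", "C5", "C3"))
    expect_setequal(firedReactions(res2), c("R1", "R2"))
})

test_that("empty seeds or empty banks give empty results", {
    res <- expandNetwork(miniBank(), character(0))
    expect_length(producibleCompounds(res), 0)
    expect_length(firedReactions(res), 0)
    res2 <- expandNetwork(miniBank()[0, ], c("C1"))
    expect_equal(producibleCompounds(res2), "C1")
})

test_that("expansion equals the naive loop-until-stable oracle", {
    set.seed(41)
    for (rep in 1:25) {
        bank <- randomBank(sample(10:80, 1), sample(10:40, 1))
        seeds <- sample(sprintf("X%03d", 1:40), sample(1:6, 1))
        want <- naiveExpand(bank, seeds)
        got <- expandNetwork(bank, seeds)
        expect_setequal(producibleCompounds(got), want$producible)
        expect_setequal(firedReactions(got), want$fired)
    }
})

test_that("the result is invariant under reaction-bank permutations", {
    set.seed(42)
    bank <- randomBank(60, 25)
    seeds <- sprintf("X%03d", 1:4)
    ref <- expandNetwork(bank, seeds)
    for (rep in 1:10) {
        sh <- bank[sample(nrow(bank)), ]
        got <- expandNetwork(sh, seeds)
        expect_setequal(producibleCompounds(got), producibleCompounds(ref))
        expect_setequal(firedReactions(got), firedReactions(ref))
    }
})

test_that("expansion is monotone in the seed set", {
    set.seed(43)
    for (rep in 1:25) {
        bank <- randomBank(sample(10:60, 1), 30)
        s1 <- sample(sprintf("X%03d", 1:30), sample(1:5, 1))
        s2 <- unique(c(s1, sample(sprintf("X%03d", 1:30), sample(1:5, 1))))
        p1 <- producibleCompounds(expandNetwork(bank, s1))
        p2 <- producibleCompounds(expandNetwork(bank, s2))
        expect_true(all(p1 %in% p2))
    }
})

test_that("expansion is idempotent and terminates within |bank| rounds", {
    set.seed(44)
    for (rep in 1:10) {
        bank <- randomBank(sample(10:60, 1), 25)
        seeds <- sample(sprintf("X%03d", 1:25), 3)
        r1 <- expandNetwork(bank, seeds)
        r2 <- expandNetwork(bank, producibleCompounds(r1))
        expect_setequal(producibleCompounds(r2), producibleCompounds(r1))
        expect_lte(length(expansionIterations(r1)), nrow(bank))
    }
})

test_that("iteration layers are disjoint and reconstruct the result", {
    set.seed(45)
    bank <- randomBank(50, 20)
    seeds <- sprintf("X%03d", 1:3)
    res <- expandNetwork(bank, seeds)
    layers <- expansionIterations(res)
    newC <- unlist(lapply(layers, `[[`, "compounds"))
    expect_false(anyDuplicated(newC) > 0)
    expect_setequal(c(seeds, newC), producibleCompounds(res))
    expect_setequal(unlist(lapply(layers, `[[`, "reactions")),
        firedReactions(res))
    # every non-seed producible compound is a product of a fired reaction
    firedProducts <- unique(unlist(
        bank$products[bank$reaction_id %in% firedReactions(res)]))
    expect_true(all(setdiff(producibleCompounds(res), seeds)
        %in% firedProducts))
    # every fired reaction had all substrates available
    for (id in firedReactions(res))
        expect_true(all(bank$substrates[[which(bank$reaction_id == id)]]
            %in% producibleCompounds(res)))
})

test_that("treatment simulations share one bank and only seeds differ", {
    fx <- generateFixtureDatabase(40, 60, randomSeed = 46)
    tab <- generateFixtureTable(fx$db, randomSeed = 46)
    sets <- scopeEcSets(tab)
    meta <- detectSeeds(buildNetwork(fx$db, sets$meta, "meta"))
    p1 <- applyMetaFilter(
        detectSeeds(buildNetwork(fx$db, sets$treatment_1, "treatment_1")), meta)
    p2 <- applyMetaFilter(
        detectSeeds(buildNetwork(fx$db, sets$treatment_2, "treatment_2")), meta)
    sims <- simulateTreatments(fx$db, sets$meta, p1, p2)
    # identical proxies give identical results
    twin <- simulateTreatments(fx$db, sets$meta, p1, p1)
    expect_setequal(producibleCompounds(twin$treatment_1),
        producibleCompounds(twin$treatment_2))
    # superset proxy gives superset closure
    extra <- setdiff(names(compoundNames(fx$db)), seedCompounds(p1))[1]
    bigger <- new("EnvironmentalProxy",
        compounds = c(seedCompounds(p1), extra),
        provenance = data.frame(
            compound = c(seedCompounds(p1), extra),
            scc_id = 1L, scc_size = 1L, stringsAsFactors = FALSE),
        scopeLabel = "treatment_1", filtered = TRUE)
    more <- simulateTreatments(fx$db, sets$meta, bigger, p2)
    expect_true(all(producibleCompounds(sims$treatment_1) %in%
        producibleCompounds(more$treatment_1)))
    # unfiltered proxies are rejected
    expect_error(simulateTreatments(fx$db, sets$meta, detectSeeds(
        buildNetwork(fx$db, sets$treatment_1, "treatment_1")), p2),
        "contract")
})

test_that("unique compounds are the two set differences", {
    r1 <- new("ExpansionResult", seeds = "A", producible = c("A", "B", "C"),
        firedReactions = character(0), iterations = list(),
        scopeLabel = "treatment_1")
    r2 <- new("ExpansionResult", seeds = "B", producible = c("B", "C", "D"),
        firedReactions = character(0), iterations = list(),
        scopeLabel = "treatment_2")
    u <- uniqueCompounds(r1, r2)
    expect_equal(u$treatment_1, "A")
    expect_equal(u$treatment_2, "D")
    same <- uniqueCompounds(r1, r1)
    expect_length(same$treatment_1, 0)
    expect_length(same$treatment_2, 0)
    set.seed(47)
    for (rep in 1:20) {
        a <- sample(LETTERS, sample(1:20, 1))
        b <- sample(LETTERS, sample(1:20, 1))
        ra <- new("ExpansionResult", seeds = character(0), producible = a,
            firedReactions = character(0), iterations = list(),
            scopeLabel = "treatment_1")
        rb <- new("ExpansionResult", seeds = character(0), producible = b,
            firedReactions = character(0), iterations = list(),
            scopeLabel = "treatment_2")
        u <- uniqueCompounds(ra, rb)
        expect_setequal(u$treatment_1, setdiff(a, b))
        expect_setequal(u$treatment_2, setdiff(b, a))
        expect_length(intersect(u$treatment_1, u$treatment_2), 0)
    }
})
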