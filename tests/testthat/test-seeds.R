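chainNet <- function(nodes, scope = "meta") {
    metabolicNetwork(data.frame(
        substrate = nodes[-length(nodes)], product = nodes[-1],
        stringsAsFactors = FALSE), scope)
}

test_that("SCCs of simple digraphs are as expected", {
    expect_equal(canonicalPartition(
        stronglyConnectedComponents(chainNet(c("C1", "C2", "C3")))$components),
        c("C1", "C2", "C3"))
    net <- metabolicNetwork(data.frame(
        substrate = c("C1", "C2", "C2"), product = c("C2", "C1", "C3")))
    expect_equal(canonicalPartition(
        stronglyConnectedComponents(net)$components), c("C1|C2", "C3"))
    empty <- metabolicNetwork(data.frame(substrate = character(0),
        product = character(0)))
    expect_length(stronglyConnectedComponents(empty)$components, 0)
})

test_that("SCC partition matches the mutual-reachability closure oracle", {
    set.seed(31)
    for (rep in 1:30) {
        net <- randomNetwork(sample(4:60, 1), p = runif(1, 0.02, 0.2))
        expect_equal(
            canonicalPartition(stronglyConnectedComponents(net)$components),
            canonicalPartition(oracleScc(net)))
    }
})

test_that("seed detection on hand-built topologies", {
    expect_setequal(seedCompounds(detectSeeds(chainNet(c("C1", "C2", "C3")))),
        "C1")
    cyc <- metabolicNetwork(data.frame(
        substrate = c("C1", "C2", "C2"), product = c("C2", "C1", "C3")))
    px <- detectSeeds(cyc)
    expect_setequal(seedCompounds(px), c("C1", "C2"))
    expect_equal(unique(seedProvenance(px)$scc_size), 2L)
    two <- metabolicNetwork(data.frame(
        substrate = c("C1", "C4"), product = c("C2", "C5")))
    expect_setequal(seedCompounds(detectSeeds(two)), c("C1", "C4"))
    expect_false(isFiltered(px))
})

test_that("per-node reachability oracle confirms detected seeds", {
    set.seed(32)
    for (rep in 1:30) {
        net <- randomNetwork(sample(4:60, 1), p = runif(1, 0.02, 0.25))
        expect_setequal(seedCompounds(detectSeeds(net)), oracleSeeds(net))
    }
})

test_that("every node is reachable from the seed set", {
    set.seed(33)
    for (rep in 1:20) {
        net <- randomNetwork(sample(4:50, 1), p = runif(1, 0.02, 0.3))
        r <- reachClosure(net)
        seeds <- seedCompounds(detectSeeds(net))
        covered <- apply(r[seeds, , drop = FALSE], 2, any)
        expect_true(all(covered))
    }
})

test_that("seeds have no incoming edge from outside their own SCC", {
    set.seed(34)
    for (rep in 1:15) {
        net <- randomNetwork(sample(5:40, 1), p = runif(1, 0.05, 0.3))
        px <- detectSeeds(net)
        m <- stronglyConnectedComponents(net)$membership
        ed <- networkEdges(net)
        for (s in seedCompounds(px)) {
            incoming <- ed$substrate[ed$product == s]
            expect_true(all(m[incoming] == m[s]))
        }
    }
})

test_that("the condensation is acyclic", {
    set.seed(35)
    for (rep in 1:15) {
        net <- randomNetwork(sample(5:50, 1), p = runif(1, 0.05, 0.3))
        m <- stronglyConnectedComponents(net)$membership
        ed <- networkEdges(net)
        cross <- m[ed$substrate] != m[ed$product]
        cg <- igraph::graph_from_data_frame(data.frame(
            from = as.character(m[ed$substrate][cross]),
            to = as.character(m[ed$product][cross])),
            vertices = as.character(unique(m)))
        expect_true(igraph::is_dag(cg))
    }
})

test_that("meta filtering is plain intersection with provenance kept", {
    t1 <- chainNet(c("C1", "C9"), scope = "treatment_1")
    meta <- chainNet(c("C1", "C2"), scope = "meta")
    filtered <- applyMetaFilter(detectSeeds(t1), detectSeeds(meta))
    expect_equal(seedCompounds(filtered), "C1")
    expect_true(isFiltered(filtered))
    expect_equal(seedProvenance(filtered)$compound, "C1")
    # disjoint sets warn and give an empty proxy
    t2 <- chainNet(c("C7", "C8"), scope = "treatment_2")
    expect_warning(
        empty <- applyMetaFilter(detectSeeds(t2), detectSeeds(meta)),
        "empty")
    expect_length(seedCompounds(empty), 0)
})

test_that("meta filter contracts reject scope and state misuse", {
    meta <- detectSeeds(chainNet(c("C1", "C2"), scope = "meta"))
    t1 <- detectSeeds(chainNet(c("C1", "C3"), scope = "treatment_1"))
    expect_error(applyMetaFilter(meta, meta), "contract")
    expect_error(applyMetaFilter(t1, t1), "contract")
    f <- applyMetaFilter(t1, meta)
    expect_error(applyMetaFilter(f, meta), "contract")
})

test_that("filter equals an independent set intersection on random inputs", {
    set.seed(36)
    for (rep in 1:20) {
        meta <- randomNetwork(sample(10:40, 1), p = 0.1, scope = "meta")
        sub <- randomNetwork(sample(10:40, 1), p = 0.1,
            scope = "treatment_1")
        pm <- detectSeeds(meta)
        ps <- detectSeeds(sub)
        got <- suppressWarnings(applyMetaFilter(ps, pm))
        expect_setequal(seedCompounds(got),
            intersect(seedCompounds(ps), seedCompounds(pm)))
    }
})

test_that("edge deletion (fragmentation) never lowers the raw seed count", {
    set.seed(37)
    for (rep in 1:15) {
        meta <- randomNetwork(sample(15:50, 1), p = 0.12, scope = "meta")
        ed <- networkEdges(meta)
        keep <- sample(nrow(ed), max(1, round(nrow(ed) * 0.5)))
        sub <- metabolicNetwork(
            data.frame(substrate = ed$substrate[keep],
                product = ed$product[keep], stringsAsFactors = FALSE),
            scopeLabel = "treatment_1")
        pm <- detectSeeds(meta)
        ps <- detectSeeds(sub)
        filtered <- suppressWarnings(applyMetaFilter(ps, pm))
        expect_gte(length(seedCompounds(ps)), length(seedCompounds(filtered)))
    }
})

test_that("resource lists are written one compound per line", {
    px <- detectSeeds(chainNet(c("C2", "C1")))
    f <- withr::local_tempfile(fileext = ".txt")
    writeResourceList(px, f)
    expect_equal(readLines(f), "C2")
})
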