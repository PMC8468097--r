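starNet <- function(nLeaves) {
    metabolicNetwork(data.frame(
        substrate = "HUB", product = sprintf("L%02d", seq_len(nLeaves)),
        stringsAsFactors = FALSE))
}

test_that("hub filter boundary: 25 neighbors retained, 26 removed", {
    keep <- filterHubs(starNet(25))
    expect_true("HUB" %in% networkNodes(keep))
    drop <- filterHubs(starNet(26))
    expect_false("HUB" %in% networkNodes(drop))
    expect_equal(nrow(networkEdges(drop)), 0L)
})

test_that("neighbor counting is undirected and multiplicity-free", {
    # 13 out-neighbors, 13 in-neighbors, plus reciprocal edges to 5 of
    # them: 26 distinct neighbors regardless of direction or parallelism
    ed <- data.frame(
        substrate = c(rep("HUB", 13), sprintf("I%02d", 1:13),
            sprintf("O%02d", 1:5)),
        product = c(sprintf("O%02d", 1:13), rep("HUB", 13),
            rep("HUB", 5)),
        stringsAsFactors = FALSE)
    net <- metabolicNetwork(ed)
    expect_false("HUB" %in% networkNodes(filterHubs(net)))
    # with one fewer in-neighbor the hub survives at exactly 25
    ed2 <- ed[ed$substrate != "I13" & ed$product != "I13", ]
    expect_true("HUB" %in% networkNodes(filterHubs(metabolicNetwork(ed2))))
})

test_that("surviving node set equals a brute-force degree scan", {
    set.seed(61)
    for (rep in 1:15) {
        net <- randomNetwork(sample(10:60, 1), p = runif(1, 0.05, 0.5))
        maxN <- sample(2:12, 1)
        got <- filterHubs(net, maxN)
        ed <- networkEdges(net)
        deg <- vapply(networkNodes(net), function(v) length(unique(
            c(ed$product[ed$substrate == v], ed$substrate[ed$product == v]))),
            integer(1))
        hubs <- names(deg)[deg > maxN]
        expect_setequal(networkNodes(got), setdiff(networkNodes(net), hubs))
        ed2 <- networkEdges(got)
        expect_false(any(ed2$substrate %in% hubs | ed2$product %in% hubs))
        # no survivor exceeded the threshold on the input graph
        expect_true(all(deg[networkNodes(got)] <= maxN))
    }
})

test_that("layout is deterministic for a fixed seed and respects dims", {
    net <- randomNetwork(20, p = 0.15)
    a <- layoutNetwork(net, dims = 2, iterations = 40, rngSeed = 7)
    b <- layoutNetwork(net, dims = 2, iterations = 40, rngSeed = 7)
    expect_identical(a@positions, b@positions)
    c3 <- layoutNetwork(net, dims = 3, iterations = 10, rngSeed = 7)
    expect_equal(ncol(c3@positions), 3L)
    expect_true(all(is.finite(c3@positions)))
})

test_that("zero iterations return the seeded initial placement", {
    net <- randomNetwork(15, p = 0.2)
    n <- length(networkNodes(net))
    lay <- layoutNetwork(net, dims = 2, iterations = 0, rngSeed = 3)
    want <- withr::with_seed(3,
        matrix(runif(n * 2, -1, 1), ncol = 2))
    expect_equal(unname(lay@positions), want)
})

test_that("force layout separates path endpoints beyond neighbors", {
    nodes <- sprintf("P%02d", 1:10)
    net <- metabolicNetwork(data.frame(substrate = nodes[-10],
        product = nodes[-1], stringsAsFactors = FALSE))
    lay <- layoutNetwork(net, dims = 2, iterations = 50, rngSeed = 5)
    pos <- lay@positions
    dEnds <- sqrt(sum((pos["P01", ] - pos["P10", ])^2))
    dAdj <- sqrt(sum((pos["P05", ] - pos["P06", ])^2))
    expect_gt(dEnds, dAdj)
})

test_that("roles classify seeds, unique compounds and shared nodes", {
    net <- metabolicNetwork(data.frame(
        substrate = c("C1", "C2"), product = c("C2", "C3"),
        stringsAsFactors = FALSE))
    px <- new("EnvironmentalProxy", compounds = "C1",
        provenance = data.frame(compound = "C1", scc_id = 1L,
            scc_size = 1L, stringsAsFactors = FALSE),
        scopeLabel = "treatment_1", filtered = TRUE)
    roles <- assignRoles(net, px, unique = "C3",
        differentialEcs = character(0))
    expect_equal(unname(roles$nodeRoles[c("C1", "C2", "C3")]),
        c("seed", "shared", "treatment_unique"))
    expect_equal(roles$edgeRoles, c("background", "background"))
    # seed wins over unique, with a log message
    expect_message(roles2 <- assignRoles(net, px, unique = c("C1", "C3"),
        differentialEcs = character(0)), "shown as seed")
    expect_equal(unname(roles2$nodeRoles["C1"]), "seed")
    # empty annotation means everything is shared
    emptyPx <- new("EnvironmentalProxy", compounds = character(0),
        provenance = data.frame(compound = character(0), scc_id = integer(0),
            scc_size = integer(0), stringsAsFactors = FALSE),
        scopeLabel = "treatment_1", filtered = TRUE)
    roles3 <- assignRoles(net, emptyPx, character(0), character(0))
    expect_true(all(roles3$nodeRoles == "shared"))
})

test_that("edge roles follow the differential-EC witnesses", {
    set.seed(62)
    fx <- generateFixtureDatabase(30, 45, randomSeed = 62)
    ecs <- unique(unlist(reactions(fx$db)$ec))
    dEcs <- sample(ecs, 10)
    net <- buildNetwork(fx$db, ecs)
    px <- detectSeeds(net)
    roles <- assignRoles(net, px, character(0), dEcs)
    want <- vapply(networkEdges(net)$ecs,
        function(e) any(e %in% dEcs), logical(1))
    expect_equal(roles$edgeRoles == "differential", want)
})

test_that("rendering writes raster and byte-stable coordinate exports", {
    net <- randomNetwork(12, p = 0.2)
    roles <- assignRoles(net, detectSeeds(net), character(0), character(0))
    lay <- layoutNetwork(net, dims = 3, iterations = 20, rngSeed = 1,
        nodeRoles = roles$nodeRoles, edgeRoles = roles$edgeRoles,
        haloPathways = list())
    d <- withr::local_tempdir()
    p1 <- file.path(d, "net.png"); j1 <- file.path(d, "net1.json")
    j2 <- file.path(d, "net2.json")
    renderNetwork(lay, net, p1, j1)
    renderNetwork(lay, net, file.path(d, "net2.png"), j2)
    expect_identical(readLines(j1), readLines(j2))
    expect_gt(file.size(p1), 0)
    parsed <- jsonlite::read_json(j1)
    expect_length(parsed$nodes, length(networkNodes(net)))
    expect_length(parsed$edges, nrow(networkEdges(net)))
})

test_that("an empty network renders a placeholder without error", {
    empty <- metabolicNetwork(data.frame(substrate = character(0),
        product = character(0)))
    lay <- layoutNetwork(empty)
    d <- withr::local_tempdir()
    expect_no_error(renderNetwork(lay, empty, file.path(d, "e.png"),
        file.path(d, "e.json")))
    expect_true(file.exists(file.path(d, "e.png")))
})

test_that("per-pathway exports are indexed 0..k-1 with sanitized names", {
    fx <- generateFixtureDatabase(25, 40, randomSeed = 63)
    ecs <- unique(unlist(reactions(fx$db)$ec))
    net <- buildNetwork(fx$db, ecs)
    lay <- layoutNetwork(net, dims = 3, iterations = 5, rngSeed = 2)
    d <- withr::local_tempdir()
    pws <- c("Naphthalene degradation", "Biotin metabolism",
        "Drug metabolism - other enzymes")
    files <- exportPathwaySubgraphs(lay, net, pws,
        compoundPathways(fx$db), d, "root")
    expect_length(files, 3)
    expect_equal(basename(files[1]),
        "3D_network_root_0_Naphthalene_degradation.json")
    expect_equal(basename(files[3]),
        "3D_network_root_2_Drug_metabolism_-_other_enzymes.json")
    expect_true(all(file.exists(files)))
})
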