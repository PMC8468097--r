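# Independent oracles and random-structure generators used across the
# suite. These deliberately use naive brute-force formulations (matrix
# transitive closure, loop-until-stable expansion, explicit
# hypergeometric sums) so they share no code path with the package.

# random directed graph as a MetabolicNetwork; no self-loops
randomNetwork <- function(n, p = 2 / n, scope = "meta") {
    nodes <- sprintf("N%03d", seq_len(n))
    adj <- matrix(stats::runif(n * n) < p, n, n)
    diag(adj) <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) == 0L) idx <- cbind(1L, 2L)  # keep at least one edge
    metabolicNetwork(data.frame(substrate = nodes[idx[, 1]],
        product = nodes[idx[, 2]], stringsAsFactors = FALSE), scope)
}

# boolean transitive closure (reflexive) by repeated squaring
reachClosure <- function(net) {
    nodes <- networkNodes(net)
    n <- length(nodes)
    ed <- networkEdges(net)
    m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    m[cbind(ed$substrate, ed$product)] <- TRUE
    diag(m) <- TRUE
    repeat {
        m2 <- (m %*% m) > 0
        if (identical(m2, m > 0)) break
        m <- m2
    }
    m > 0
}

# SCC partition from pairwise mutual reachability
oracleScc <- function(net) {
    r <- reachClosure(net)
    mutual <- r & t(r)
    groups <- apply(mutual, 1, function(row) paste(which(row), collapse = ","))
    unname(split(rownames(r), groups))
}

# seed rule: s is a seed iff no node outside SCC(s) reaches s
oracleSeeds <- function(net) {
    r <- reachClosure(net)
    nodes <- rownames(r)
    nodes[vapply(seq_along(nodes), function(s) {
        reachers <- which(r[, s])
        all(r[s, reachers])   # everyone reaching s is mutually reachable
    }, logical(1))]
}

# canonical form of a partition for set-of-sets comparison
canonicalPartition <- function(parts) {
    unname(sort(vapply(parts, function(x) paste(sort(x), collapse = "|"),
        character(1))))
}

# random reaction bank (directed, 1-3 substrates/products, no overlap)
randomBank <- function(nReactions, nCompounds) {
    cpd <- sprintf("X%03d", seq_len(nCompounds))
    rows <- lapply(seq_len(nReactions), function(i) {
        s <- sample(cpd, sample(1:3, 1))
        p <- sample(setdiff(cpd, s), sample(1:3, 1))
        data.frame(reaction_id = sprintf("B%04d", i),
            base_id = sprintf("B%04d", i),
            ec = I(list(sprintf("9.9.9.%d", i))),
            substrates = I(list(s)), products = I(list(p)),
            reversible = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

# naive expansion: sweep the bank in its given order until stable
naiveExpand <- function(bank, seeds) {
    pool <- unique(seeds)
    fired <- character(0)
    repeat {
        new <- FALSE
        for (i in seq_len(nrow(bank))) {
            id <- bank$reaction_id[i]
            if (id %in% fired) next
            if (all(bank$substrates[[i]] %in% pool)) {
                fired <- c(fired, id)
                add <- setdiff(bank$products[[i]], pool)
                pool <- c(pool, add)
                new <- TRUE
            }
        }
        if (!new) break
    }
    list(producible = pool, fired = fired)
}

# exact hypergeometric upper-tail P(X >= k) by explicit summation
oracleFisherP <- function(k, K, n, N) {
    i <- k:min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by hand
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# tiny valid differential table with a given association split
randomTable <- function(n1, n2, n0) {
    n <- n1 + n2 + n0
    assoc <- sample(c(rep("treatment_1", n1), rep("treatment_2", n2),
        rep("not_associated", n0)))
    differentialTable(data.frame(
        ec_id = sprintf("1.2.3.%d", seq_len(n)),
        log_fc = stats::rnorm(n), p_value = stats::runif(n),
        adj_p_value = stats::runif(n), association = assoc,
        stringsAsFactors = FALSE))
}
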