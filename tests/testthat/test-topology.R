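starGraph <- function(nLeaves = 4) {
    g <- igraph::make_star(nLeaves + 1, mode = "undirected")
    igraph::V(g)$name <- c("C", paste0("L", seq_len(nLeaves)))
    g
}

test_that("degree distribution is P(k) = N_k / N and sums to one", {
    st <- degreeDistribution(starGraph(4))
    expect_equal(st@degrees, c(1L, 4L))
    expect_equal(st@values, c(0.8, 0.2))

    k4 <- igraph::make_full_graph(4)
    igraph::V(k4)$name <- LETTERS[1:4]
    dd <- degreeDistribution(k4)
    expect_equal(dd@degrees, 3L)
    expect_equal(dd@values, 1.0)

    for (seed in 1:5) {
        A <- randomAdjacency(12, 0.3, seed)
        expect_equal(sum(degreeDistribution(adjacencyToIgraph(A))@values), 1)
    }
})

test_that("clustering coefficients match the exhaustive triangle oracle", {
    tri <- namedGraph(rbind(c("A", "B"), c("B", "C"), c("C", "A")))
    expect_equal(unname(clusteringCoefficients(tri)), rep(1, 3))
    expect_equal(unname(clusteringCoefficients(starGraph(4))), rep(0, 5))
    for (seed in 1:10) {
        A <- randomAdjacency(10, 0.4, seed)
        expect_equal(clusteringCoefficients(adjacencyToIgraph(A)),
                     oracleClustering(A))
    }
})

test_that("neighborhood connectivity equals mean neighbor degree", {
    cn <- neighborhoodConnectivity(starGraph(4))
    expect_equal(unname(cn["C"]), 1)
    expect_equal(unname(cn[paste0("L", 1:4)]), rep(4, 4))

    ring <- igraph::make_ring(7)
    igraph::V(ring)$name <- paste0("R", 1:7)
    expect_equal(unname(neighborhoodConnectivity(ring)), rep(2, 7))

    for (seed in 1:10) {
        A <- randomAdjacency(12, 0.3, seed)
        expect_equal(neighborhoodConnectivity(adjacencyToIgraph(A)),
                     oracleNeighborhoodConnectivity(A))
    }
})

test_that("betweenness matches shortest-path oracles on small graphs", {
    path <- namedGraph(rbind(c("A", "B"), c("B", "C")))
    b <- betweennessCentrality(path)
    expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

    st <- betweennessCentrality(starGraph(4))
    expect_equal(unname(st["C"]), 1)
    expect_equal(unname(st[paste0("L", 1:4)]), rep(0, 4))

    ring5 <- igraph::make_ring(5)
    igraph::V(ring5)$name <- paste0("R", 1:5)
    expect_equal(unname(betweennessCentrality(ring5)), rep(1 / 6, 5),
                 tolerance = 1e-12)
})

test_that("closeness is component-wise (n_c - 1) / sum of distances", {
    path <- namedGraph(rbind(c("A", "B"), c("B", "C")))
    cc <- closenessCentrality(path)
    expect_equal(unname(cc[c("A", "B", "C")]), c(2 / 3, 1, 2 / 3))

    expect_equal(unname(closenessCentrality(starGraph(4))["C"]), 1)

    ring5 <- igraph::make_ring(5)
    igraph::V(ring5)$name <- paste0("R", 1:5)
    expect_equal(unname(closenessCentrality(ring5)), rep(4 / 6, 5))
})

test_that("betweenness and closeness equal brute-force oracles on random graphs", {
    # randomized sweep: 200 instances of graphs with <= 10 nodes
    cases <- expand.grid(seed = 1:50, n = c(6, 8, 9, 10))
    for (i in seq_len(nrow(cases))) {
        A <- randomAdjacency(cases$n[i], 0.35, cases$seed[i] + 1000 * cases$n[i])
        g <- adjacencyToIgraph(A)
        expect_equal(betweennessCentrality(g), oracleBetweenness(A),
                     tolerance = 1e-10)
        expect_equal(suppressWarnings(closenessCentrality(g)),
                     oracleCloseness(A), tolerance = 1e-12)
    }
})

test_that("eigenvector centrality satisfies A v = lambda v with unit norm", {
    k4 <- igraph::make_full_graph(4)
    igraph::V(k4)$name <- LETTERS[1:4]
    expect_equal(unname(as.numeric(eigenvectorCentrality(k4))), rep(0.5, 4),
                 tolerance = 1e-9)

    ev <- eigenvectorCentrality(starGraph(4))
    expect_equal(unname(ev["C"]), 1 / sqrt(2), tolerance = 1e-8)
    expect_equal(unname(ev[paste0("L", 1:4)]), rep(sqrt(1 / 8), 4),
                 tolerance = 1e-8)
    expect_equal(attr(ev, "lambda"), 2, tolerance = 1e-9)

    for (seed in 1:10) {
        A <- randomAdjacency(8, 0.45, seed)
        g <- adjacencyToIgraph(A)
        got <- suppressWarnings(eigenvectorCentrality(g))
        expect_equal(as.numeric(got), unname(oracleEigenvector(A)),
                     tolerance = 1e-8)
        expect_lt(attr(got, "residual"), 1e-8)
        expect_equal(sum(got[got > 0]^2), 1, tolerance = 1e-10)
    }
})

test_that("power-law fits recover exact laws and flag degenerate input", {
    k <- 1:20
    f <- fitPowerLaw(new("DegreeCurve", degrees = as.integer(k),
                         values = k^-2, statistic = "exact"))
    expect_equal(f@exponent, 2, tolerance = 1e-10)
    expect_equal(abs(f@r), 1, tolerance = 1e-10)
    expect_lt(f@stderr, 1e-10)

    const <- fitPowerLaw(new("DegreeCurve", degrees = as.integer(k),
                             values = rep(0.5, 20), statistic = "const"))
    expect_equal(const@exponent, 0)

    expect_error(
        fitPowerLaw(new("DegreeCurve", degrees = c(1L, 2L),
                        values = c(0.5, 0.25), statistic = "short")),
        "fewer than 3")
})

test_that("regime classification follows the exponent thresholds", {
    expect_identical(classifyRegime(0.76), "hierarchical/modular")
    expect_identical(classifyRegime(2.5), "scale-free (hub-integrated)")
    expect_identical(classifyRegime(3.5), "hub-independent")
    expect_identical(classifyRegime(2), "scale-free (hub-integrated)")
    expect_identical(classifyRegime(3), "scale-free (hub-integrated)")
})

test_that("all six statistics are invariant under node relabeling", {
    A <- randomAdjacency(12, 0.35, 77)
    g <- adjacencyToIgraph(A)
    m1 <- nodeMetrics(g)
    set.seed(123)
    perm <- sample(nrow(A))
    B <- A[perm, perm]
    m2 <- nodeMetrics(adjacencyToIgraph(B))
    m1 <- m1[order(m1$node), ]
    m2 <- m2[order(m2$node), ]
    for (col in c("degree", "clustering", "neighborhood", "betweenness",
                  "closeness", "eigenvector"))
        expect_equal(m1[[col]], m2[[col]], tolerance = 1e-8,
                     label = paste("metric", col))
})

test_that("degree-averaged curves exclude low-degree nodes where undefined", {
    # on a k-regular graph the CN curve is the single point (k, k)
    ring <- igraph::make_ring(8)
    igraph::V(ring)$name <- paste0("R", 1:8)
    m <- nodeMetrics(ring)
    cn <- degreeCurve(m, "neighborhood")
    expect_equal(cn@degrees, 2L)
    expect_equal(cn@values, 2)

    st <- starGraph(4)
    mc <- degreeCurve(nodeMetrics(st), "clustering")
    expect_equal(mc@degrees, 4L)   # leaves (k=1) excluded from C(k)
})
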