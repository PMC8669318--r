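cliqueGraph <- function(prefix, n) t(combn(paste0(prefix, seq_len(n)), 2))

test_that("core numbers equal the independent peeling oracle", {
    k4 <- igraph::make_full_graph(4)
    igraph::V(k4)$name <- LETTERS[1:4]
    expect_equal(unname(coreNumbers(k4)), rep(3L, 4))

    tree <- igraph::make_tree(10, children = 2, mode = "undirected")
    igraph::V(tree)$name <- paste0("T", 1:10)
    expect_equal(unname(coreNumbers(tree)), rep(1L, 10))

    # exhaustive-style sweep over random graphs up to 20 nodes
    for (n in c(8, 12, 15, 20)) for (seed in 1:10) {
        A <- randomAdjacency(n, 0.3, seed + 31 * n)
        expect_equal(coreNumbers(adjacencyToIgraph(A)),
                     oracleCoreNumbers(A))
    }
})

test_that("vertex weights follow the closed-neighborhood k-core rule", {
    k5 <- igraph::make_full_graph(5)
    igraph::V(k5)$name <- LETTERS[1:5]
    expect_equal(unname(vertexWeights(k5)$weight), rep(4, 5))  # 4 x 1.0

    k2 <- namedGraph(rbind(c("A", "B")))
    expect_equal(unname(vertexWeights(k2)$weight), c(1, 1))    # 1 x 1.0

    st <- igraph::make_star(5, mode = "undirected")
    igraph::V(st)$name <- c("C", paste0("L", 1:4))
    w <- vertexWeights(st)$weight
    # closed neighborhood of the center is the star itself: highest core
    # k = 1, density 4/10
    expect_equal(unname(w["C"]), 0.4)

    iso <- st + igraph::vertex("Z")
    expect_equal(unname(vertexWeights(iso)$weight["Z"]), 0)
})

test_that("seeded expansion admits neighbors above the weight threshold", {
    # two 5-cliques joined through a low-weight path: one complex per clique
    el <- rbind(cliqueGraph("A", 5), cliqueGraph("B", 5),
                c("A1", "P1"), c("P1", "P2"), c("P2", "B1"))
    g <- namedGraph(el)
    raw <- predictComplexes(g)
    big <- Filter(function(x) x@nNodes >= 5, raw)
    expect_length(big, 2)
    expect_setequal(members(big[[1]]), paste0("A", 1:5))
    expect_setequal(members(big[[2]]), paste0("B", 1:5))

    # uniform weights on a cycle: the whole cycle is one complex
    ring <- igraph::make_ring(6)
    igraph::V(ring)$name <- paste0("R", 1:6)
    expect_setequal(members(predictComplexes(ring)[[1]]), paste0("R", 1:6))

    # cutoff 0 requires strictly greater weight than the seed, so nothing
    # can join and every complex is a singleton
    chain <- namedGraph(rbind(cliqueGraph("C", 4), c("C1", "X"),
                              c("X", "Y")))
    raw0 <- predictComplexes(chain, params = mcodeParams(nodeScoreCutoff = 0))
    expect_true(all(vapply(raw0, function(x) x@nNodes, integer(1)) == 1L))
    expect_length(raw0, igraph::vcount(chain))
})

test_that("post-processing applies k-core filter and idempotent haircut", {
    el <- rbind(cliqueGraph("K", 5), c("K1", "PEND"))
    g <- namedGraph(el)
    cplx <- predictComplexes(g, params = mcodeParams(nodeScoreCutoff = 1))[[1]]
    expect_true("PEND" %in% members(cplx))
    post <- postprocessComplex(cplx, g)
    expect_setequal(members(post), paste0("K", 1:5))
    # haircut is a fixpoint: a second pass changes nothing
    again <- postprocessComplex(post, g)
    expect_setequal(members(again), members(post))
    expect_equal(again@score, post@score)

    # a 3-node path has no 2-core and is discarded
    p3 <- namedGraph(rbind(c("A", "B"), c("B", "C")))
    raw <- predictComplexes(p3)[[1]]
    expect_null(postprocessComplex(raw, p3))
})

test_that("module scores reproduce the published density-times-size values", {
    expect_equal(scoreComplex(11, 44), 8.8)
    expect_equal(truncateScore(scoreComplex(41, 103)), 5.15)
    expect_equal(truncateScore(scoreComplex(76, 176)), 4.69)
    expect_equal(truncateScore(scoreComplex(65, 140)), 4.37)
    expect_equal(truncateScore(scoreComplex(15, 34)), 4.85)
    # display truncates, never rounds
    expect_identical(formatScore(4.375), "4.37")
    expect_identical(formatScore(4.857), "4.85")
    # every clique scores exactly n
    for (n in 2:12) expect_equal(scoreComplex(n, n * (n - 1) / 2), n)
    expect_error(scoreComplex(1, 0), "at least 2 nodes")
    expect_error(scoreComplex(4, 7), "outside")
})

test_that("module selection keeps scores above threshold in stable order", {
    mk <- function(seed, n, score) {
        dens <- score / n
        e <- as.integer(round(dens * n * (n - 1) / 2))
        new("MCODEComplex", members = paste0(seed, seq_len(n)), seed = paste0(seed, 1),
            nNodes = as.integer(n), nEdges = e,
            density = score / n, score = score)
    }
    pool <- list(mk("a", 11, 8.8), mk("b", 41, 5.15), mk("c", 15, 4.85),
                 mk("d", 76, 4.69), mk("e", 65, 4.37), mk("f", 10, 3.9))
    sel <- selectModules(pool, minScore = 4)
    expect_length(sel, 5)
    expect_equal(vapply(sel, moduleScore, numeric(1)),
                 c(8.8, 5.15, 4.85, 4.69, 4.37))

    expect_warning(out <- selectModules(list(mk("x", 5, 3.2)), minScore = 4),
                   "no module")
    expect_length(out, 0)

    tie <- list(mk("g", 8, 4.5), mk("h", 10, 4.5))
    expect_equal(selectModules(tie, 4)[[1]]@nNodes, 10L)
})

test_that("complexes are disjoint with fluff off and members stay in-graph", {
    sim <- generatePlantedComplexes(80, 0.05, list(c(6, 1), c(8, 0.9)),
                                    seed = 21)
    g <- igraph::graph_from_data_frame(sim$edges, directed = FALSE)
    mods <- mcode(g)
    allMembers <- unlist(lapply(mods, members))
    expect_equal(anyDuplicated(allMembers), 0)
    expect_true(all(allMembers %in% igraph::V(g)$name))
})

test_that("planted near-cliques are recovered with high Jaccard", {
    # single planted 6-clique on a sparse 100-node background
    one <- generatePlantedComplexes(100, 0.02, list(c(6, 1)), seed = 4)
    g1 <- igraph::graph_from_data_frame(one$edges, directed = FALSE)
    mods1 <- selectModules(mcode(g1), minScore = 4)
    expect_gte(length(mods1), 1)
    expect_equal(max(vapply(mods1, function(m)
        jaccard(members(m), one$plants[[1]]), numeric(1))), 1.0)

    # two plants of density 0.9, sizes 8 and 10
    two <- generatePlantedComplexes(100, 0.02,
                                    list(c(8, 0.9), c(10, 0.9)), seed = 4)
    g2 <- igraph::graph_from_data_frame(two$edges, directed = FALSE)
    mods2 <- mcode(g2)
    for (plant in two$plants) {
        best <- max(vapply(mods2, function(m) jaccard(members(m), plant),
                           numeric(1)))
        expect_gte(best, 0.8)
    }

    # no plants: nothing clears the score threshold on a thin background
    none <- generatePlantedComplexes(100, 0.02, seed = 4)
    g3 <- igraph::graph_from_data_frame(none$edges, directed = FALSE)
    expect_length(suppressWarnings(selectModules(mcode(g3), minScore = 4)), 0)
})
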