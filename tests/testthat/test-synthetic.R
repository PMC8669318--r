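test_that("generators are pure functions of their seed", {
    a <- generateMultisourceInteractome(30, 4, 40, seed = 17)
    b <- generateMultisourceInteractome(30, 4, 40, seed = 17)
    expect_identical(a, b)
    expect_false(identical(
        a$records,
        generateMultisourceInteractome(30, 4, 40, seed = 18)$records))

    expect_identical(generateHierarchicalScaleFree(200, 2, 0.5, seed = 3),
                     generateHierarchicalScaleFree(200, 2, 0.5, seed = 3))
    expect_identical(generatePlantedComplexes(50, 0.05, list(c(5, 1)), seed = 2),
                     generatePlantedComplexes(50, 0.05, list(c(5, 1)), seed = 2))
    g <- sprintf("G%04d", 1:50)
    expect_identical(generateAnnotations(g, g[1:8], seed = 9),
                     generateAnnotations(g, g[1:8], seed = 9))

    # written source files are byte-identical across runs
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- generateMultisourceInteractome(20, 3, 20, seed = 5, outDir = d1)$files
    f2 <- generateMultisourceInteractome(20, 3, 20, seed = 5, outDir = d2)$files
    for (i in seq_along(f1))
        expect_identical(readLines(f1[[i]]), readLines(f2[[i]]))
})

test_that("multi-source emission guarantees truth recovery and decoy rejection", {
    sim <- generateMultisourceInteractome(50, 5, 100, seed = 31)
    net <- buildConsensus(sim$records, minSources = 2)
    expect_equal(numEdges(net), 100)

    # every decoy pair appears in exactly one source
    key <- paste(pmin(sim$records$geneA, sim$records$geneB),
                 pmax(sim$records$geneA, sim$records$geneB))
    trueKey <- paste(pmin(sim$truth$geneA, sim$truth$geneB),
                     pmax(sim$truth$geneA, sim$truth$geneB))
    decoySupport <- table(key[!key %in% trueKey])
    expect_true(all(decoySupport == 1))
    # and none of them reaches the consensus
    e <- networkEdges(net)
    netKey <- paste(pmin(e$geneA, e$geneB), pmax(e$geneA, e$geneB))
    expect_length(intersect(netKey, names(decoySupport)), 0)
})

test_that("growth model yields heavy-tailed P(k) and decaying C(k)", {
    hs <- generateHierarchicalScaleFree(5000, 3, 0.8, seed = 11)
    g <- igraph::graph_from_data_frame(hs, directed = FALSE)
    # fit over well-sampled degrees: the single-observation tail plateau is
    # censored (minCount = 2)
    f <- fitPowerLaw(degreeDistribution(g), minCount = 2)
    expect_gte(f@exponent, 2.0)
    expect_lte(f@exponent, 3.5)
    expect_lt(f@r, 0)

    # triad closure makes log C(k) decrease with log k
    m <- suppressWarnings(nodeMetrics(g))
    ck <- degreeCurve(m, "clustering")
    keep <- ck@values > 0
    expect_lt(cor(log(ck@degrees[keep]), log(ck@values[keep])), 0)

    # m = 1 yields a tree
    tree <- generateHierarchicalScaleFree(10, 1, 0.8, seed = 2)
    expect_equal(nrow(tree), 9)
    gt <- igraph::graph_from_data_frame(tree, directed = FALSE)
    expect_equal(igraph::components(gt)$no, 1)
})

test_that("planted complexes respect block sizes and densities", {
    sim <- generatePlantedComplexes(60, 0, list(c(6, 1), c(8, 1)), seed = 8)
    g <- igraph::graph_from_data_frame(sim$edges, directed = FALSE)
    expect_equal(lengths(sim$plants), c(6L, 8L))
    expect_length(intersect(sim$plants[[1]], sim$plants[[2]]), 0)
    # density-1 blocks are cliques; zero background means nothing else
    expect_equal(igraph::ecount(g), choose(6, 2) + choose(8, 2))
    expect_error(generatePlantedComplexes(10, 0.1, list(c(2, 1))), ">= 3")
    expect_error(generatePlantedComplexes(10, 0.1, list(c(6, 1), c(6, 1))),
                 "node budget")
})

test_that("planted annotations drive the downstream detectors", {
    universe <- sprintf("G%04d", 1:200)
    moduleGenes <- universe[1:10]
    ann <- generateAnnotations(universe, moduleGenes,
                               plantedCoverage = 0.8, backgroundRate = 0.1,
                               seed = 13)
    res <- enrich(moduleGenes, ann$terms, universe)
    planted <- res[res$term == "PLANTED", ]
    expect_equal(planted$overlap, 8)           # coverage 8/10
    expect_true(planted$significant)
    expect_lte(planted$pAdj, 0.05)
    expect_identical(res$term[1], "PLANTED")

    # exact 60/40 class split per gene
    prof <- diseaseClassProfile(universe[5], ann$disease)
    expect_equal(sort(prof@perGene$percentage), c(40, 60))
})

test_that("the full pipeline runs end to end on generated data", {
    sim <- generateMultisourceInteractome(80, 5, 300, seed = 101,
                                          nDecoysPerSource = 30)
    net <- buildConsensus(sim$records, minSources = 2)
    metrics <- suppressWarnings(nodeMetrics(net))
    expect_equal(nrow(metrics), numNodes(net))
    expect_true(all(metrics$clustering >= 0 & metrics$clustering <= 1))
    expect_true(all(metrics$betweenness >= 0 & metrics$betweenness <= 1))

    sel <- selectKeyNodes(net, q = 0.05, metrics = metrics)
    expect_equal(sel@count, floor(0.05 * numNodes(net)))
    scr <- knockoutScreen(net, bottleneckHubs(sel))
    expect_equal(nrow(scr), length(bottleneckHubs(sel)))
    expect_equal(scr$edgesRemoved,
                 unname(metrics$degree[match(scr$node, metrics$node)]))

    mods <- mcode(net)
    if (length(mods) > 0) {
        ct <- crosstalkMatrix(net, bottleneckHubs(sel), mods)
        expect_equal(ct@totals, unname(as.integer(rowSums(ct@counts))))
    }
    rep <- fitReport(net, metrics = metrics)
    expect_true(all(c("exponent", "r") %in% names(rep)))
})
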