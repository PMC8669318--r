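#' Generate a seeded multi-source interactome with a planted truth network
#'
#' Emulates per-database interaction exports with controlled overlap.  Every
#' true edge is force-emitted into two distinct randomly chosen sources (so
#' consensus at minimum support 2 recovers the truth exactly) and into each
#' remaining source independently with probability \code{pEmit}.  Decoy
#' edges, disjoint from the truth, appear in exactly one source each and
#' therefore never reach two-source support.
#'
#' @param nGenes number of gene symbols (G0001, ...)
#' @param nSources number of source databases (>= 2)
#' @param nTrueEdges number of planted true interactions
#' @param pEmit per-source emission probability for true edges beyond the
#'   two forced ones (default 0.4)
#' @param nDecoysPerSource single-source decoy edges per source (default 20)
#' @param seed integer RNG seed; identical seeds give identical output
#' @param outDir optional directory; one TSV per source is written there
#' @return list with \code{records} (geneA, geneB, source), \code{truth}
#'   (geneA, geneB), \code{sources} (records split by source) and, when
#'   written, \code{files}
#' @examples
#' sim <- generateMultisourceInteractome(30, 5, 40, seed = 1)
#' net <- buildConsensus(sim$records, minSources = 2)
#' numEdges(net) == nrow(sim$truth)
#' @export
generateMultisourceInteractome <- function(nGenes, nSources = 5L,
                                           nTrueEdges, pEmit = 0.4,
                                           nDecoysPerSource = 20L,
                                           seed = 1L, outDir = NULL) {
    stopifnot(nSources >= 2, pEmit >= 0, pEmit <= 1)
    maxPairs <- nGenes * (nGenes - 1) / 2
    if (nTrueEdges + nSources * nDecoysPerSource > maxPairs)
        stop("too many edges requested for ", nGenes, " genes")
    .withSeed(seed, {
        genes <- sprintf("G%04d", seq_len(nGenes))
        pairIdx <- sample.int(maxPairs, nTrueEdges + nSources * nDecoysPerSource)
        pairs <- .indexToPair(pairIdx, nGenes)
        truth <- data.frame(geneA = genes[pairs[, 1]],
                            geneB = genes[pairs[, 2]],
                            stringsAsFactors = FALSE)[seq_len(nTrueEdges), ]
        decoys <- data.frame(geneA = genes[pairs[, 1]],
                             geneB = genes[pairs[, 2]],
                             stringsAsFactors = FALSE)[-seq_len(nTrueEdges), ]
        srcIds <- sprintf("S%d", seq_len(nSources))
        recs <- list()
        for (i in seq_len(nTrueEdges)) {
            forced <- sample(srcIds, 2)
            rest <- setdiff(srcIds, forced)
            extra <- rest[runif(length(rest)) < pEmit]
            for (s in c(forced, extra))
                recs[[length(recs) + 1L]] <-
                    c(truth$geneA[i], truth$geneB[i], s)
        }
        if (nDecoysPerSource > 0) {
            decoySrc <- rep(srcIds, each = nDecoysPerSource)
            for (i in seq_len(nrow(decoys)))
                recs[[length(recs) + 1L]] <-
                    c(decoys$geneA[i], decoys$geneB[i], decoySrc[i])
        }
        m <- do.call(rbind, recs)
        records <- data.frame(geneA = m[, 1], geneB = m[, 2], source = m[, 3],
                              stringsAsFactors = FALSE)
        out <- list(records = records, truth = truth,
                    sources = split(records, records$source))
        if (!is.null(outDir)) {
            dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
            out$files <- vapply(names(out$sources), function(s) {
                f <- file.path(outDir, paste0(s, ".tsv"))
                write.table(out$sources[[s]][, c("geneA", "geneB")], f,
                            sep = "\t", quote = FALSE, row.names = FALSE)
                f
            }, character(1))
        }
        out
    })
}

# map linear indices 1..n(n-1)/2 to unordered pairs (i < j)
.indexToPair <- function(idx, n) {
    # row i (1-based) covers indices (i-1)*n - i*(i+1)/2 + (i+1..n - i)*...:
    # solve by cumulative counts
    counts <- (n - 1):1
    ends <- cumsum(counts)
    i <- findInterval(idx - 1, c(0, ends), rightmost.closed = FALSE)
    j <- idx - c(0, ends)[i] + i
    cbind(i, j)
}

#' Generate a hierarchical scale-free network
#'
#' Growth model combining preferential attachment with triad closure: each
#' new node attaches its first edge preferentially by degree; each further
#' edge closes a triangle through a neighbor of the previous target with
#' probability \code{triadProb}, otherwise attaches preferentially.  The
#' result has a heavy-tailed degree distribution and a clustering
#' coefficient that decreases with degree — the fingerprints of
#' hierarchical scale-free topology.
#'
#' @param n number of nodes (> m)
#' @param m edges added per new node (>= 1); m = 1 yields a tree
#' @param triadProb probability of a triad-closure step (default 0.8)
#' @param seed integer RNG seed
#' @return data.frame edge list (geneA, geneB) over symbols G0001, ...
#' @export
generateHierarchicalScaleFree <- function(n, m = 3L, triadProb = 0.8,
                                          seed = 1L) {
    stopifnot(n > m, m >= 1, triadProb >= 0, triadProb <= 1)
    .withSeed(seed, {
        genes <- sprintf("G%04d", seq_len(n))
        m0 <- m + 1L
        ea <- eb <- integer(0)
        for (i in seq_len(m0 - 1L))                 # seed clique
            for (j in seq((i + 1L), m0)) { ea <- c(ea, i); eb <- c(eb, j) }
        # endpoint multiset for preferential attachment
        ends <- c(ea, eb)
        adj <- vector("list", n)
        for (e in seq_along(ea)) {
            adj[[ea[e]]] <- c(adj[[ea[e]]], eb[e])
            adj[[eb[e]]] <- c(adj[[eb[e]]], ea[e])
        }
        for (v in seq(m0 + 1L, n)) {
            targets <- integer(0)
            prev <- NA_integer_
            for (j in seq_len(m)) {
                cand <- NA_integer_
                if (j > 1L && !is.na(prev) && runif(1) < triadProb) {
                    pool <- setdiff(adj[[prev]], c(v, targets))
                    if (length(pool))
                        cand <- pool[sample.int(length(pool), 1L)]
                }
                if (is.na(cand)) {                  # preferential attachment
                    repeat {
                        cand <- ends[sample.int(length(ends), 1L)]
                        if (!cand %in% c(v, targets)) break
                    }
                }
                targets <- c(targets, cand)
                prev <- cand
            }
            for (t in targets) {
                ea <- c(ea, v); eb <- c(eb, t)
                ends <- c(ends, v, t)
                adj[[v]] <- c(adj[[v]], t)
                adj[[t]] <- c(adj[[t]], v)
            }
        }
        data.frame(geneA = genes[ea], geneB = genes[eb],
                   stringsAsFactors = FALSE)
    })
}

#' Generate a background network with planted dense complexes
#'
#' Carves disjoint node blocks out of \code{nNodes} and wires each block
#' internally at its stated density; background edges at \code{bgDensity}
#' connect all other node pairs except pairs spanning two different planted
#' blocks, which stay non-adjacent so that each planted complex remains a
#' separate, identifiable unit (cross-talk between plants can only flow
#' through background nodes).  The plant map is returned so module-recovery
#' can be scored.
#'
#' @param nNodes total node count
#' @param bgDensity background edge probability (e.g. 0.02)
#' @param complexes list of \code{c(size, density)} pairs; sizes must be
#'   >= 3 and sum to at most \code{nNodes}
#' @param seed integer RNG seed
#' @return list with \code{edges} (geneA, geneB) and \code{plants} (list of
#'   member-symbol vectors)
#' @export
generatePlantedComplexes <- function(nNodes, bgDensity = 0.02,
                                     complexes = list(), seed = 1L) {
    sizes <- vapply(complexes, function(x) as.integer(x[1]), integer(1))
    dens <- vapply(complexes, function(x) as.numeric(x[2]), numeric(1))
    if (any(sizes < 3)) stop("planted complex sizes must be >= 3")
    if (sum(sizes) > nNodes) stop("planted blocks exceed the node budget")
    stopifnot(all(dens >= 0 & dens <= 1), bgDensity >= 0, bgDensity <= 1)
    .withSeed(seed, {
        genes <- sprintf("G%04d", seq_len(nNodes))
        block <- integer(nNodes)                    # 0 = background
        at <- 1L
        plants <- vector("list", length(sizes))
        for (b in seq_along(sizes)) {
            idx <- seq(at, at + sizes[b] - 1L)
            block[idx] <- b
            plants[[b]] <- genes[idx]
            at <- at + sizes[b]
        }
        pr <- utils::combn(nNodes, 2)
        sameBlock <- block[pr[1, ]] == block[pr[2, ]] & block[pr[1, ]] > 0
        crossBlock <- block[pr[1, ]] != block[pr[2, ]] &
            block[pr[1, ]] > 0 & block[pr[2, ]] > 0
        p <- rep(bgDensity, ncol(pr))
        p[crossBlock] <- 0
        if (length(dens) > 0 && any(sameBlock))
            p[sameBlock] <- dens[block[pr[1, sameBlock]]]
        keep <- runif(ncol(pr)) < p
        edges <- data.frame(geneA = genes[pr[1, keep]],
                            geneB = genes[pr[2, keep]],
                            stringsAsFactors = FALSE)
        list(edges = edges, plants = plants)
    })
}

#' Generate annotation and disease tables with planted structure
#'
#' Builds a gene-set collection containing one planted term that covers a
#' designated gene subset at a stated coverage (against a low background
#' inclusion rate elsewhere in the universe), plus random background terms;
#' and a gene-disease-class table in which each gene's diseases are split
#' across classes at exact stated proportions.
#'
#' @param genes universe gene symbols
#' @param plantedGenes subset the planted term should capture
#' @param plantedCoverage fraction of \code{plantedGenes} included in the
#'   planted term (default 0.8)
#' @param backgroundRate probability that a non-designated universe gene
#'   enters the planted term (default 0.05)
#' @param nTerms number of random background terms (default 20)
#' @param termSizeRange integer range of background term sizes
#' @param classes disease-class labels
#' @param classProportions per-gene proportion of diseases in each class
#'   (sums to 1; exact counts are planted, not sampled)
#' @param nDiseasesPerGene diseases associated with each gene (default 10)
#' @param seed integer RNG seed
#' @return list with \code{terms} (a [TermCollection-class], planted term id
#'   \code{"PLANTED"}) and \code{disease} (gene, disease, class, score)
#' @export
generateAnnotations <- function(genes, plantedGenes,
                                plantedCoverage = 0.8,
                                backgroundRate = 0.05,
                                nTerms = 20L, termSizeRange = c(5L, 25L),
                                classes = c("ClassA", "ClassB"),
                                classProportions = c(0.6, 0.4),
                                nDiseasesPerGene = 10L, seed = 1L) {
    stopifnot(all(plantedGenes %in% genes),
              length(classes) == length(classProportions),
              abs(sum(classProportions) - 1) < 1e-9)
    nPlant <- round(plantedCoverage * length(plantedGenes))
    if (nPlant < 1) stop("planted coverage infeasible for subset size ",
                         length(plantedGenes))
    .withSeed(seed, {
        inPlant <- sample(plantedGenes, nPlant)
        others <- setdiff(genes, plantedGenes)
        inPlant <- c(inPlant, others[runif(length(others)) < backgroundRate])
        ids <- c("PLANTED", sprintf("T%03d", seq_len(nTerms)))
        descs <- c("planted enriched term",
                   rep("random background term", nTerms))
        sets <- c(list(inPlant),
                  lapply(seq_len(nTerms), function(i)
                      sample(genes, sample(seq(termSizeRange[1],
                                               termSizeRange[2]), 1))))
        terms <- new("TermCollection", ids = ids, descriptions = descs,
                     genes = sets, namespace = "synthetic")
        # exact per-gene class counts via cumulative rounding
        cuts <- diff(c(0, round(cumsum(classProportions) * nDiseasesPerGene)))
        disease <- do.call(rbind, lapply(genes, function(gn) {
            data.frame(gene = gn,
                       disease = sprintf("D_%s_%02d", gn,
                                         seq_len(nDiseasesPerGene)),
                       class = rep(classes, times = cuts),
                       score = round(runif(nDiseasesPerGene), 3),
                       stringsAsFactors = FALSE)
        }))
        list(terms = terms, disease = disease)
    })
}
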