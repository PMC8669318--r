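#' Construct MCODE parameters
#'
#' @param nodeScoreCutoff neighbor admission threshold (default 0.2)
#' @param haircut trim singly-connected members (default TRUE)
#' @param fluff add dense-neighborhood boundary nodes (default FALSE)
#' @param fluffDensityCutoff closed-neighborhood density threshold for fluff
#'   (default 0.1)
#' @param kCore minimum core a complex must contain (default 2)
#' @param maxDepth breadth-first expansion radius from the seed (default 100)
#' @param minScore module score threshold for [selectModules()] (default 4)
#' @return an [MCODEParams-class]
#' @export
mcodeParams <- function(nodeScoreCutoff = 0.2, haircut = TRUE, fluff = FALSE,
                        fluffDensityCutoff = 0.1, kCore = 2L,
                        maxDepth = 100L, minScore = 4) {
    new("MCODEParams", nodeScoreCutoff = nodeScoreCutoff, haircut = haircut,
        fluff = fluff, fluffDensityCutoff = fluffDensityCutoff,
        kCore = as.integer(kCore), maxDepth = as.integer(maxDepth),
        minScore = minScore)
}

#' k-core numbers of all nodes
#'
#' The core number of a node is the largest k such that the node belongs to
#' the k-core (the maximal subgraph in which every node has at least k
#' neighbors within the subgraph), obtained by iterative minimum-degree
#' pruning.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return named integer vector
#' @export
coreNumbers <- function(net) {
    g <- .asGraph(net)
    setNames(as.integer(igraph::coreness(g)), igraph::V(g)$name)
}

# density 2E/(n(n-1)) of an igraph; 0 for n < 2
.graphDensity <- function(g) {
    n <- igraph::vcount(g)
    if (n < 2) return(0)
    2 * igraph::ecount(g) / (n * (n - 1))
}

# highest k-core of a graph: the induced subgraph on nodes of maximal
# coreness, together with that k
.highestKCore <- function(g) {
    if (igraph::ecount(g) == 0) return(list(k = 0L, graph = g))
    core <- igraph::coreness(g)
    kmax <- max(core)
    list(k = as.integer(kmax),
         graph = igraph::induced_subgraph(g, which(core == kmax)))
}

#' MCODE vertex weights
#'
#' Stage one of the algorithm.  For each node v, the subgraph induced on v
#' plus its neighbors (the closed neighborhood) is formed; the weight of v
#' is the k of that subgraph's highest k-core multiplied by the density
#' 2E/(n(n-1)) of that core subgraph.  Nodes in locally dense regions thus
#' score high; degree-0 nodes score 0.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return list with components \code{weight} (named numeric) and
#'   \code{coreNumber} (named integer, the global core numbers)
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- LETTERS[1:5]
#' vertexWeights(g)$weight       # 4 x 1.0 = 4 for every clique member
#' @export
vertexWeights <- function(net) {
    g <- .asGraph(net)
    nms <- igraph::V(g)$name
    w <- vapply(seq_len(igraph::vcount(g)), function(i) {
        nb <- igraph::neighbors(g, i)
        if (length(nb) == 0) return(0)
        sub <- igraph::induced_subgraph(g, c(i, as.integer(nb)))
        hk <- .highestKCore(sub)
        hk$k * .graphDensity(hk$graph)
    }, numeric(1))
    list(weight = setNames(w, nms), coreNumber = coreNumbers(g))
}

#' MCODE complex prediction (seeded expansion)
#'
#' Stage two.  Unvisited nodes are taken as seeds in order of weight
#' descending (ties by symbol ascending).  From each seed a breadth-first
#' expansion admits an unvisited neighbor when its weight exceeds
#' seed weight times (1 - nodeScoreCutoff); expansion is capped at
#' \code{maxDepth} steps from the seed.  Admitted nodes are marked visited,
#' so complexes from one run are disjoint.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param weights result of [vertexWeights()] (computed if NULL)
#' @param params an [MCODEParams-class]
#' @return list of [MCODEComplex-class] (raw, before [postprocessComplex()])
#' @export
predictComplexes <- function(net, weights = NULL, params = mcodeParams()) {
    g <- .asGraph(net)
    if (is.null(weights)) weights <- vertexWeights(g)
    w <- weights$weight
    nms <- igraph::V(g)$name
    stopifnot(all(nms %in% names(w)))
    w <- w[nms]
    visited <- setNames(rep(FALSE, length(nms)), nms)
    seedOrder <- nms[order(-w, nms)]
    adj <- igraph::adjacent_vertices(g, nms)
    adj <- lapply(adj, function(v) nms[as.integer(v)])
    names(adj) <- nms
    out <- list()
    for (seed in seedOrder) {
        if (visited[seed]) next
        threshold <- w[seed] * (1 - params@nodeScoreCutoff)
        membersV <- seed
        visited[seed] <- TRUE
        frontier <- seed
        depth <- 0L
        while (length(frontier) > 0 && depth < params@maxDepth) {
            nextFrontier <- character()
            for (v in frontier) {
                for (u in adj[[v]]) {
                    if (!visited[u] && w[u] > threshold) {
                        visited[u] <- TRUE
                        membersV <- c(membersV, u)
                        nextFrontier <- c(nextFrontier, u)
                    }
                }
            }
            frontier <- nextFrontier
            depth <- depth + 1L
        }
        out[[length(out) + 1L]] <- .makeComplex(g, membersV, seed)
    }
    out
}

# build an MCODEComplex from a member set
.makeComplex <- function(g, membersV, seed) {
    sub <- igraph::induced_subgraph(g, membersV)
    n <- length(membersV)
    e <- igraph::ecount(sub)
    dens <- if (n >= 2) 2 * e / (n * (n - 1)) else 0
    new("MCODEComplex", members = membersV, seed = seed,
        nNodes = as.integer(n), nEdges = as.integer(e),
        density = dens, score = dens * n)
}

#' MCODE post-processing (k-core filter, haircut, fluff)
#'
#' Stage three.  A complex is discarded when its induced subgraph contains
#' no \code{kCore}-core.  Haircut iteratively removes members with fewer
#' than 2 internal neighbors until a fixpoint (so it is idempotent);
#' complexes reduced below 3 members are discarded.  Fluff, when enabled,
#' then adds non-member neighbors whose closed-neighborhood density in the
#' full network exceeds \code{fluffDensityCutoff} (fluffed complexes may
#' overlap).
#'
#' @param cplx an [MCODEComplex-class] from [predictComplexes()]
#' @param net the network the complex was predicted on
#' @param params an [MCODEParams-class]
#' @return the post-processed [MCODEComplex-class], or NULL when discarded
#' @export
postprocessComplex <- function(cplx, net, params = mcodeParams()) {
    g <- .asGraph(net)
    membersV <- cplx@members
    sub <- igraph::induced_subgraph(g, membersV)
    if (igraph::ecount(sub) == 0 ||
        max(igraph::coreness(sub)) < params@kCore)
        return(NULL)
    if (params@haircut) {
        repeat {
            degIn <- igraph::degree(sub)
            drop <- igraph::V(sub)$name[degIn < 2]
            if (length(drop) == 0) break
            membersV <- setdiff(membersV, drop)
            if (length(membersV) < 3) return(NULL)
            sub <- igraph::induced_subgraph(g, membersV)
        }
    }
    if (params@fluff) {
        boundary <- setdiff(
            unique(unlist(lapply(membersV, function(v)
                igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]))),
            membersV)
        dens <- vapply(boundary, function(v) {
            nb <- igraph::neighbors(g, v)
            sub2 <- igraph::induced_subgraph(g, c(v, as.integer(nb)))
            .graphDensity(sub2)
        }, numeric(1))
        membersV <- c(membersV, boundary[dens > params@fluffDensityCutoff])
    }
    seed <- if (cplx@seed %in% membersV) cplx@seed else membersV[1]
    .makeComplex(g, membersV, seed)
}

#' Module score from node and edge counts
#'
#' The M-score of a complex: density times size, (2E/(n(n-1))) * n.  Full
#' precision is returned; published scores are displayed truncated to two
#' decimals (see [truncateScore()]).
#'
#' @param n number of nodes (>= 2)
#' @param edges number of internal edges, in [0, n(n-1)/2]
#' @return numeric(1)
#' @examples
#' scoreComplex(11, 44)   # 8.8
#' scoreComplex(41, 103)  # 5.15 after 2-decimal truncation
#' @export
scoreComplex <- function(n, edges) {
    if (n < 2) stop("a complex needs at least 2 nodes")
    if (edges < 0 || edges > n * (n - 1) / 2)
        stop("edge count outside [0, n(n-1)/2]")
    (2 * edges / (n * (n - 1))) * n
}

#' Filter and order detected modules by score
#'
#' Keeps complexes with score strictly above \code{minScore}, ordered by
#' score descending (ties: larger n first, then seed symbol ascending),
#' optionally truncated to the top \code{topN}.
#'
#' @param complexes list of [MCODEComplex-class]
#' @param minScore score threshold (default 4, i.e. keep score > 4)
#' @param topN optional cap on the number of modules returned
#' @return ordered list of [MCODEComplex-class] (possibly empty, with a
#'   warning)
#' @export
selectModules <- function(complexes, minScore = 4, topN = NULL) {
    scores <- vapply(complexes, function(x) x@score, numeric(1))
    keep <- complexes[scores > minScore]
    if (length(keep) == 0) {
        warning("no module exceeds the score threshold ", minScore)
        return(list())
    }
    sc <- vapply(keep, function(x) x@score, numeric(1))
    nn <- vapply(keep, function(x) x@nNodes, integer(1))
    sd <- vapply(keep, function(x) x@seed, character(1))
    keep <- keep[order(-sc, -nn, sd)]
    if (!is.null(topN)) keep <- head(keep, topN)
    keep
}

#' Run the full MCODE pipeline
#'
#' Vertex weighting, seeded complex prediction and post-processing in one
#' call.  Returns all surviving complexes ordered by score descending; use
#' [selectModules()] to apply the score threshold.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param params an [MCODEParams-class]
#' @return list of [MCODEComplex-class]
#' @export
mcode <- function(net, params = mcodeParams()) {
    g <- .asGraph(net)
    weights <- vertexWeights(g)
    raw <- predictComplexes(g, weights, params)
    done <- Filter(Negate(is.null),
                   lapply(raw, postprocessComplex, net = g, params = params))
    if (length(done) == 0) return(list())
    sc <- vapply(done, function(x) x@score, numeric(1))
    nn <- vapply(done, function(x) x@nNodes, integer(1))
    sd <- vapply(done, function(x) x@seed, character(1))
    done[order(-sc, -nn, sd)]
}

#' Export detected modules as a table
#'
#' @param complexes list of [MCODEComplex-class]
#' @return data.frame with columns module, seed, n, edges, density, score,
#'   scoreDisplay (2-decimal truncation), members (comma-separated)
#' @export
modulesTable <- function(complexes) {
    if (length(complexes) == 0)
        return(data.frame(module = integer(), seed = character(),
                          n = integer(), edges = integer(),
                          density = numeric(), score = numeric(),
                          scoreDisplay = character(), members = character(),
                          stringsAsFactors = FALSE))
    data.frame(
        module = seq_along(complexes),
        seed = vapply(complexes, function(x) x@seed, character(1)),
        n = vapply(complexes, function(x) x@nNodes, integer(1)),
        edges = vapply(complexes, function(x) x@nEdges, integer(1)),
        density = vapply(complexes, function(x) x@density, numeric(1)),
        score = vapply(complexes, function(x) x@score, numeric(1)),
        scoreDisplay = vapply(complexes, function(x) formatScore(x@score),
                              character(1)),
        members = vapply(complexes,
                         function(x) paste(sort(x@members), collapse = ","),
                         character(1)),
        stringsAsFactors = FALSE)
}
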