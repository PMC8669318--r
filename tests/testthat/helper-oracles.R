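# Brute-force oracles, deliberately independent of the package's own code
# paths (and of igraph's centrality routines): everything here works from a
# plain adjacency matrix.

# random simple graph as a named adjacency matrix
randomAdjacency <- function(n, p, seed) {
    set.seed(seed)
    A <- matrix(0L, n, n)
    idx <- which(upper.tri(A))
    on <- idx[runif(length(idx)) < p]
    A[on] <- 1L
    A <- A + t(A)
    dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
    A
}

adjacencyToIgraph <- function(A) {
    igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# distances and shortest-path counts via adjacency powers: the number of
# walks of length d between i and j equals (A^d)_ij, and at the first d
# where it is nonzero those walks are exactly the shortest paths
distSigma <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n); diag(D) <- 0
    S <- diag(1, n)
    P <- diag(1, n)
    for (d in seq_len(n)) {
        P <- P %*% A
        newly <- is.infinite(D) & P > 0
        D[newly] <- d
        S[newly] <- P[newly]
        if (!any(is.infinite(D[upper.tri(D)])) ) break
    }
    list(D = D, S = S)
}

oracleBetweenness <- function(A) {
    n <- nrow(A)
    ds <- distSigma(A)
    D <- ds$D; S <- ds$S
    out <- numeric(n)
    for (v in seq_len(n)) {
        tot <- 0
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            if (i == v || j == v || is.infinite(D[i, j])) next
            if (D[i, v] + D[v, j] == D[i, j])
                tot <- tot + S[i, v] * S[v, j] / S[i, j]
        }
        out[v] <- tot / ((n - 1) * (n - 2) / 2)
    }
    names(out) <- rownames(A)
    out
}

oracleCloseness <- function(A) {
    n <- nrow(A)
    D <- distSigma(A)$D
    out <- numeric(n)
    for (i in seq_len(n)) {
        comp <- which(is.finite(D[i, ]))
        out[i] <- if (length(comp) == 1) 0
                  else (length(comp) - 1) / sum(D[i, comp])
    }
    names(out) <- rownames(A)
    out
}

oracleClustering <- function(A) {
    n <- nrow(A)
    out <- numeric(n)
    for (i in seq_len(n)) {
        nb <- which(A[i, ] > 0)
        k <- length(nb)
        if (k < 2) { out[i] <- 0; next }
        m <- sum(A[nb, nb]) / 2
        out[i] <- 2 * m / (k * (k - 1))
    }
    names(out) <- rownames(A)
    out
}

oracleNeighborhoodConnectivity <- function(A) {
    deg <- rowSums(A)
    out <- vapply(seq_len(nrow(A)), function(i) {
        nb <- which(A[i, ] > 0)
        if (length(nb) == 0) NA_real_ else mean(deg[nb])
    }, numeric(1))
    names(out) <- rownames(A)
    out
}

oracleEigenvector <- function(A) {
    # restrict to the largest connected component, dense eigendecomposition
    D <- distSigma(A)$D
    compOf <- integer(nrow(A)); cid <- 0L
    for (i in seq_len(nrow(A))) if (compOf[i] == 0L) {
        cid <- cid + 1L
        compOf[is.finite(D[i, ])] <- cid
    }
    big <- which(compOf == which.max(tabulate(compOf)))
    ev <- eigen(A[big, big, drop = FALSE], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    out <- numeric(nrow(A))
    out[big] <- v / sqrt(sum(v^2))
    names(out) <- rownames(A)
    out
}

# independent k-core peeling
oracleCoreNumbers <- function(A) {
    n <- nrow(A)
    alive <- rep(TRUE, n)
    core <- integer(n)
    k <- 0L
    while (any(alive)) {
        repeat {
            lowIdx <- which(alive)[rowSums(A[alive, alive, drop = FALSE]) <= k]
            if (length(lowIdx) == 0) break
            core[lowIdx] <- k
            alive[lowIdx] <- FALSE
            if (!any(alive)) break
        }
        k <- k + 1L
    }
    names(core) <- rownames(A)
    core
}

# hypergeometric upper tail by explicit enumeration of all module subsets
oracleHypergeomTail <- function(N, K, n, x) {
    subsets <- utils::combn(N, n)
    inTerm <- colSums(subsets <= K)   # term genes are 1..K of the universe
    mean(inTerm >= x)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small named igraph from an edge matrix
namedGraph <- function(el) {
    igraph::graph_from_edgelist(el, directed = FALSE)
}
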