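#' Degree distribution P(k)
#'
#' P(k) = N_k / N, where N_k is the number of nodes of degree k and N the
#' number of nodes in the network.  Only degrees present in the network are
#' reported; the values sum to 1.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return a [DegreeCurve-class] with statistic "P(k)"
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' degreeDistribution(g)
#' @export
degreeDistribution <- function(net) {
    g <- .asGraph(net)
    if (igraph::vcount(g) == 0) stop("empty network")
    k <- igraph::degree(g)
    tab <- table(k)
    new("DegreeCurve",
        degrees = as.integer(names(tab)),
        values = as.numeric(tab) / igraph::vcount(g),
        counts = as.integer(tab),
        statistic = "P(k)")
}

#' Per-node clustering coefficients
#'
#' C_i = 2 m_i / (k_i (k_i - 1)), the fraction of a node's neighbor pairs
#' that are themselves connected (m_i = edges among the neighbors).  Nodes
#' of degree < 2 have C defined as 0.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return named numeric vector over all nodes
#' @export
clusteringCoefficients <- function(net) {
    g <- .asGraph(net)
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    cc[igraph::degree(g) < 2] <- 0
    setNames(cc, igraph::V(g)$name)
}

#' Per-node neighborhood connectivity
#'
#' The mean degree of a node's neighbors.  Equivalent, when averaged over
#' all nodes of degree k, to the conditional mean sum_q q P(q|k).
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return named numeric vector (NA for isolated nodes, which cannot occur
#'   in a consensus network)
#' @export
neighborhoodConnectivity <- function(net) {
    g <- .asGraph(net)
    k <- igraph::degree(g)
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    nbSum <- as.numeric(A %*% k)
    out <- ifelse(k > 0, nbSum / k, NA_real_)
    setNames(out, igraph::V(g)$name)
}

#' Per-node betweenness centrality
#'
#' The fraction of shortest paths between all other node pairs that pass
#' through the node (endpoints excluded), normalized by (N-1)(N-2)/2 so
#' values lie in [0, 1].
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return named numeric vector
#' @export
betweennessCentrality <- function(net) {
    g <- .asGraph(net)
    b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    setNames(as.numeric(b), igraph::V(g)$name)
}

#' Per-node closeness centrality
#'
#' Computed within each connected component as (n_c - 1) / sum_j d_ij where
#' n_c is the component size, so values lie in (0, 1] and disconnected
#' graphs stay bounded.  Singleton components get closeness 0 with a
#' warning.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return named numeric vector
#' @export
closenessCentrality <- function(net) {
    g <- .asGraph(net)
    comp <- igraph::components(g)
    out <- numeric(igraph::vcount(g))
    names(out) <- igraph::V(g)$name
    if (any(comp$csize == 1))
        warning("singleton component(s): closeness set to 0")
    for (ci in seq_len(comp$no)) {
        idx <- which(comp$membership == ci)
        if (length(idx) == 1) { out[idx] <- 0; next }
        d <- igraph::distances(g, v = idx, to = idx)
        out[idx] <- (length(idx) - 1) / rowSums(d)
    }
    out
}

#' Per-node eigenvector centrality
#'
#' The principal eigenvector of the adjacency matrix, A v = lambda v,
#' computed by shifted power iteration on the largest connected component
#' (shift +1 guarantees convergence on bipartite components).  Entries are
#' nonnegative with unit L2 norm over the component analyzed; nodes outside
#' the largest component are set to 0 with a warning.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param tol convergence tolerance on the iterate (default 1e-10)
#' @param maxIter maximum iterations (default 1000)
#' @return named numeric vector; attributes \code{lambda} (the leading
#'   eigenvalue) and \code{residual} (max |A v - lambda v|)
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, maxIter = 1000L) {
    g <- .asGraph(net)
    comp <- igraph::components(g)
    out <- numeric(igraph::vcount(g))
    names(out) <- igraph::V(g)$name
    if (comp$no > 1)
        warning("graph is disconnected; eigenvector centrality computed ",
                "on the largest component, other nodes set to 0")
    idx <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, idx)
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    n <- nrow(A)
    v <- rep(1 / sqrt(n), n)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        w <- as.numeric(A %*% v) + v      # (A + I) v: same eigenvectors
        w <- w / sqrt(sum(w^2))
        if (max(abs(w - v)) < tol) { v <- w; converged <- TRUE; break }
        v <- w
    }
    lambda <- sum(v * as.numeric(A %*% v))        # Rayleigh quotient
    residual <- max(abs(as.numeric(A %*% v) - lambda * v))
    if (!converged && residual > 1e-8)
        stop("eigenvector iteration did not converge; residual = ",
             format(residual))
    v <- abs(v)
    out[idx] <- v / sqrt(sum(v^2))
    attr(out, "lambda") <- lambda
    attr(out, "residual") <- residual
    out
}

#' All per-node topological statistics at once
#'
#' Computes degree, clustering coefficient, neighborhood connectivity,
#' betweenness, closeness and eigenvector centrality for every node.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @return data.frame with columns node, degree, clustering, neighborhood,
#'   betweenness, closeness, eigenvector (one row per node)
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, C - A, C - D)
#' nodeMetrics(g)
#' @export
nodeMetrics <- function(net) {
    g <- .asGraph(net)
    ev <- suppressWarnings(eigenvectorCentrality(g))
    data.frame(
        node = igraph::V(g)$name,
        degree = as.integer(igraph::degree(g)),
        clustering = unname(clusteringCoefficients(g)),
        neighborhood = unname(neighborhoodConnectivity(g)),
        betweenness = unname(betweennessCentrality(g)),
        closeness = unname(suppressWarnings(closenessCentrality(g))),
        eigenvector = unname(as.numeric(ev)),
        stringsAsFactors = FALSE)
}

#' Degree-averaged curve of a node statistic
#'
#' Averages a statistic over all nodes sharing a degree, the form in which
#' clustering, neighborhood connectivity and the centralities are fitted
#' against degree.  For the clustering curve, nodes of degree < 2 (where C
#' is undefined and reported as 0 per node) are excluded.
#'
#' @param metrics result of [nodeMetrics()]
#' @param statistic one of "clustering", "neighborhood", "betweenness",
#'   "closeness", "eigenvector"
#' @return a [DegreeCurve-class]
#' @export
degreeCurve <- function(metrics,
                        statistic = c("clustering", "neighborhood",
                                      "betweenness", "closeness",
                                      "eigenvector")) {
    statistic <- match.arg(statistic)
    df <- metrics
    if (statistic == "clustering") df <- df[df$degree >= 2, , drop = FALSE]
    if (nrow(df) == 0) stop("no nodes qualify for the ", statistic, " curve")
    means <- tapply(df[[statistic]], df$degree, mean)
    cnts <- tapply(df[[statistic]], df$degree, length)
    new("DegreeCurve",
        degrees = as.integer(names(means)),
        values = as.numeric(means),
        counts = as.integer(cnts),
        statistic = statistic)
}

#' Fit a power law to a degree curve by log-log least squares
#'
#' Ordinary least squares of log10(value) on log10(degree) over points with
#' strictly positive values at degrees >= \code{minDegree}.  The exponent is
#' reported as the positive decay exponent (minus the slope); \code{r} is
#' the Pearson correlation of the log-transformed data; \code{stderr} the
#' standard error of the slope.
#'
#' On sampled curves the tail degrees observed only once form a flat
#' plateau at 1/N that biases the slope toward zero; setting
#' \code{minCount = 2} restricts the fit to well-sampled degrees (requires
#' the curve to carry per-degree counts, as curves built by
#' [degreeDistribution()] and [degreeCurve()] do).
#'
#' @param curve a [DegreeCurve-class]
#' @param minDegree smallest degree admitted to the fit (default 1)
#' @param minCount smallest per-degree node count admitted (default 1,
#'   i.e. no censoring)
#' @return a [PowerLawFit-class]
#' @examples
#' k <- 1:20
#' fitPowerLaw(new("DegreeCurve", degrees = k, values = k^-2,
#'                 statistic = "exact law"))
#' @export
fitPowerLaw <- function(curve, minDegree = 1L, minCount = 1L) {
    keep <- curve@degrees >= minDegree & curve@values > 0 & curve@degrees > 0
    if (minCount > 1L) {
        if (length(curve@counts) == 0)
            stop("minCount > 1 requires a curve with per-degree counts")
        keep <- keep & curve@counts >= minCount
    }
    x <- log10(curve@degrees[keep])
    y <- log10(curve@values[keep])
    if (length(x) < 3) stop("fewer than 3 usable points for the fit")
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[2])
    # exact laws fit perfectly; the summary warning for that case is benign
    se <- unname(suppressWarnings(summary(fit))$coefficients[2, 2])
    r <- if (sd(y) == 0 || sd(x) == 0) NA_real_ else cor(x, y)
    new("PowerLawFit",
        exponent = -slope, stderr = se, r = r,
        nPoints = length(x),
        fitRange = c(min(curve@degrees[keep]), max(curve@degrees[keep])),
        statistic = curve@statistic)
}

#' Classify the degree-distribution regime from its decay exponent
#'
#' Networks with P(k) ~ k^-gamma fall in three regimes: gamma < 2 indicates
#' a hierarchical, module-dominated organization; 2 <= gamma <= 3 a
#' scale-free topology in which smaller hubs integrate with a few large
#' ones; gamma > 3 a regime where hubs are unrelated and scale-free
#' character is lost.
#'
#' @param gamma finite decay exponent of the P(k) power law
#' @return one of "hierarchical/modular", "scale-free (hub-integrated)",
#'   "hub-independent"
#' @examples
#' classifyRegime(0.76)
#' classifyRegime(2.5)
#' @export
classifyRegime <- function(gamma) {
    stopifnot(is.finite(gamma))
    if (gamma < 2) "hierarchical/modular"
    else if (gamma <= 3) "scale-free (hub-integrated)"
    else "hub-independent"
}

#' Power-law fit report over all degree curves
#'
#' Fits P(k) and the five degree-averaged statistic curves and collects the
#' exponents, standard errors and correlations in one table.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param metrics optional precomputed [nodeMetrics()] table
#' @param minDegree smallest degree admitted to the fits
#' @return data.frame with one row per curve: curve, exponent, stderr, r,
#'   nPoints, kMin, kMax (curves with < 3 usable points are skipped)
#' @export
fitReport <- function(net, metrics = NULL, minDegree = 1L) {
    if (is.null(metrics)) metrics <- nodeMetrics(net)
    curves <- list(`P(k)` = degreeDistribution(net))
    for (s in c("clustering", "neighborhood", "betweenness", "closeness",
                "eigenvector"))
        curves[[s]] <- tryCatch(degreeCurve(metrics, s), error = function(e) NULL)
    rows <- lapply(names(curves), function(nm) {
        cv <- curves[[nm]]
        if (is.null(cv)) return(NULL)
        f <- tryCatch(fitPowerLaw(cv, minDegree), error = function(e) NULL)
        if (is.null(f)) return(NULL)
        data.frame(curve = nm, exponent = f@exponent, stderr = f@stderr,
                   r = f@r, nPoints = f@nPoints,
                   kMin = f@fitRange[1], kMax = f@fitRange[2],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
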