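#' Select the top fraction of nodes by a metric
#'
#' Returns floor(q * N) node symbols ranked by the metric descending, ties
#' broken by symbol ascending so the selection is deterministic.
#'
#' @param metrics a [nodeMetrics()] table (or any data.frame with columns
#'   \code{node} and the chosen metric)
#' @param key ranking metric, \code{"degree"} or \code{"betweenness"}
#' @param q top fraction in (0, 1); default 0.01 (the top 1 percent)
#' @return character vector of floor(q * N) symbols in rank order
#' @examples
#' m <- data.frame(node = LETTERS[1:5], degree = c(4, 9, 2, 9, 1))
#' selectTopFraction(m, "degree", q = 0.4)
#' @export
selectTopFraction <- function(metrics, key = c("degree", "betweenness"),
                              q = 0.01) {
    key <- match.arg(key)
    stopifnot(q > 0, q < 1)
    n <- floor(q * nrow(metrics))
    if (n < 1) stop("fraction too small: floor(q * N) = 0")
    ord <- order(-metrics[[key]], metrics$node)
    metrics$node[ord][seq_len(n)]
}

#' Intersect hub and bottleneck lists into bottleneck-hubs
#'
#' Bottleneck-hubs (Bn-H) are the nodes present in both the top-degree (hub)
#' and top-betweenness (bottleneck) lists; the set differences give the
#' non-Bn-H hubs and the non-hub bottlenecks.
#'
#' @param hubs ordered hub symbols
#' @param bottlenecks ordered bottleneck symbols (same length)
#' @param fraction the selection fraction, kept as metadata (NA if unknown)
#' @return a [RankedSelection-class]
#' @export
identifyBottleneckHubs <- function(hubs, bottlenecks, fraction = NA_real_) {
    if (length(hubs) == 0 || length(bottlenecks) == 0)
        stop("hub and bottleneck lists must be non-empty")
    if (length(hubs) != length(bottlenecks))
        stop("hub and bottleneck lists must have equal length")
    new("RankedSelection",
        fraction = fraction, count = length(hubs),
        hubs = hubs, bottlenecks = bottlenecks,
        bottleneckHubs = intersect(hubs, bottlenecks),
        hubOnly = setdiff(hubs, bottlenecks),
        bottleneckOnly = setdiff(bottlenecks, hubs))
}

#' Select hubs, bottlenecks and bottleneck-hubs from a network
#'
#' Convenience wrapper: ranks by degree and by betweenness, takes the top
#' fraction of each, and intersects.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param q top fraction (default 0.01)
#' @param metrics optional precomputed [nodeMetrics()] table
#' @return a [RankedSelection-class]
#' @export
selectKeyNodes <- function(net, q = 0.01, metrics = NULL) {
    if (is.null(metrics)) metrics <- nodeMetrics(net)
    identifyBottleneckHubs(
        selectTopFraction(metrics, "degree", q),
        selectTopFraction(metrics, "betweenness", q),
        fraction = q)
}

#' Single-node knockout experiment
#'
#' Removes one node (and its incident edges) from the network, recomputes
#' the degree distribution and betweenness centrality on the remainder, and
#' summarizes the perturbation: the change in connected-component count, the
#' number of edges removed (the node's intact degree), and the mean and
#' maximum absolute change in betweenness over the surviving nodes.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param node symbol of the node to remove
#' @return a [KnockoutResult-class]
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- c("HUB", paste0("L", 1:4))
#' knockout(g, "HUB")
#' @export
knockout <- function(net, node) {
    g <- .asGraph(net)
    if (!node %in% igraph::V(g)$name)
        stop("node '", node, "' is not in the network")
    cbBefore <- betweennessCentrality(g)
    compBefore <- igraph::components(g)$no
    deg <- as.integer(igraph::degree(g, v = node))
    g2 <- igraph::delete_vertices(g, node)
    cbAfter <- betweennessCentrality(g2)
    surv <- names(cbAfter)
    delta <- abs(cbAfter[surv] - cbBefore[surv])
    new("KnockoutResult",
        removed = node,
        nComponentsDelta = as.integer(igraph::components(g2)$no - compBefore),
        edgesRemoved = deg,
        meanAbsDeltaCB = if (length(delta)) mean(delta) else 0,
        maxAbsDeltaCB = if (length(delta)) max(delta) else 0,
        degreeCurveAfter = degreeDistribution(g2))
}

#' Systematic knockout screen
#'
#' Runs one independent [knockout()] per listed node — each removal starts
#' from the intact network — and ranks the results by mean absolute change
#' in betweenness, descending.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param nodes symbols to remove, one at a time
#' @return data.frame with columns node, edgesRemoved, nComponentsDelta,
#'   meanAbsDeltaCB, maxAbsDeltaCB, ordered by meanAbsDeltaCB descending
#' @export
knockoutScreen <- function(net, nodes) {
    if (length(nodes) == 0)
        return(data.frame(node = character(), edgesRemoved = integer(),
                          nComponentsDelta = integer(),
                          meanAbsDeltaCB = numeric(),
                          maxAbsDeltaCB = numeric(),
                          stringsAsFactors = FALSE))
    rows <- lapply(nodes, function(v) {
        ko <- knockout(net, v)
        data.frame(node = ko@removed, edgesRemoved = ko@edgesRemoved,
                   nComponentsDelta = ko@nComponentsDelta,
                   meanAbsDeltaCB = ko@meanAbsDeltaCB,
                   maxAbsDeltaCB = ko@maxAbsDeltaCB,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(-out$meanAbsDeltaCB, out$node), , drop = FALSE]
}
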