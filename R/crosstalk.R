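#' Interaction strength between a bottleneck-hub and a module
#'
#' Counts the consensus-network edges joining the hub to the module's
#' members.  When the hub is itself a member, only its edges to the other
#' members are counted (self-exclusion).
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param hub node symbol (must be in the network)
#' @param module an [MCODEComplex-class] or a character vector of members
#' @return integer(1) edge count
#' @export
interactionStrength <- function(net, hub, module) {
    g <- .asGraph(net)
    if (!hub %in% igraph::V(g)$name)
        stop("hub '", hub, "' is not in the network")
    membersV <- if (is(module, "MCODEComplex")) module@members else module
    membersV <- setdiff(intersect(membersV, igraph::V(g)$name), hub)
    if (length(membersV) == 0) return(0L)
    nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, hub))]
    length(intersect(nb, membersV))
}

#' Bottleneck-hub by module cross-talk matrix
#'
#' Tabulates [interactionStrength()] for every (bottleneck-hub, module)
#' pair, with per-row totals and membership flags; rows are ordered by total
#' descending (ties by symbol).
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param bnhs bottleneck-hub symbols (rows)
#' @param modules list of [MCODEComplex-class] or of member vectors; names
#'   are used as column labels (defaults to M1, M2, ...)
#' @return a [CrosstalkMatrix-class]
#' @export
crosstalkMatrix <- function(net, bnhs, modules) {
    if (length(bnhs) == 0 || length(modules) == 0)
        stop("bottleneck-hub and module lists must be non-empty")
    g <- .asGraph(net)
    labels <- names(modules)
    if (is.null(labels) || any(!nzchar(labels)))
        labels <- paste0("M", seq_along(modules))
    memberList <- lapply(modules, function(m)
        if (is(m, "MCODEComplex")) m@members else m)
    counts <- t(vapply(bnhs, function(h)
        vapply(memberList, function(m)
            as.integer(interactionStrength(g, h, m)), integer(1)),
        integer(length(modules))))
    dimnames(counts) <- list(bnhs, labels)
    membership <- t(vapply(bnhs, function(h)
        vapply(memberList, function(m) h %in% m, logical(1)),
        logical(length(modules))))
    dimnames(membership) <- dimnames(counts)
    totals <- as.integer(rowSums(counts))
    ord <- order(-totals, bnhs)
    new("CrosstalkMatrix",
        counts = counts[ord, , drop = FALSE],
        totals = totals[ord],
        membership = membership[ord, , drop = FALSE])
}

#' Cross-talk matrix as a data.frame with a totals column
#'
#' @param x a [CrosstalkMatrix-class]
#' @return data.frame: node, one column per module, total
#' @export
crosstalkTable <- function(x) {
    df <- data.frame(node = rownames(x@counts), as.data.frame(x@counts),
                     total = x@totals, stringsAsFactors = FALSE,
                     row.names = NULL, check.names = FALSE)
    df
}

#' Common connector nodes of the bottleneck-hubs
#'
#' Finds nodes adjacent to at least \code{k} of the given bottleneck-hubs —
#' candidate mediators that tie the key nodes together.
#'
#' @param net a [ConsensusNetwork-class] or igraph
#' @param bnhs bottleneck-hub symbols
#' @param k minimum number of bottleneck-hub neighbors (default 2)
#' @param excludeBnhs drop the bottleneck-hubs themselves from the result
#'   (default TRUE)
#' @return data.frame with columns node, nBnhNeighbors, ordered descending
#' @export
commonConnectors <- function(net, bnhs, k = 2L, excludeBnhs = TRUE) {
    g <- .asGraph(net)
    bnhs <- intersect(bnhs, igraph::V(g)$name)
    cnt <- setNames(rep(0L, igraph::vcount(g)), igraph::V(g)$name)
    for (h in bnhs) {
        nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, h))]
        cnt[nb] <- cnt[nb] + 1L
    }
    if (excludeBnhs) cnt <- cnt[setdiff(names(cnt), bnhs)]
    cnt <- cnt[cnt >= k]
    out <- data.frame(node = names(cnt), nBnhNeighbors = as.integer(cnt),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$nBnhNeighbors, out$node), , drop = FALSE]
}
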