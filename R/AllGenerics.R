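#' Number of nodes in a network
#' @param x a [ConsensusNetwork-class] or igraph object
#' @return integer(1)
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges in a network
#' @param x a [ConsensusNetwork-class] or igraph object
#' @return integer(1)
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Node symbols of a network
#' @param x a [ConsensusNetwork-class] or igraph object
#' @return character vector of gene symbols
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network
#' @param x a [ConsensusNetwork-class]
#' @return data.frame with columns geneA, geneB (and support where present)
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Per-edge source-support counts
#' @param x a [ConsensusNetwork-class]
#' @return integer vector aligned with [networkEdges()]
#' @export
setGeneric("edgeSupport", function(x) standardGeneric("edgeSupport"))

#' Underlying igraph object
#' @param x a [ConsensusNetwork-class]
#' @return the igraph object
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Member genes of a complex or selection
#' @param x an [MCODEComplex-class]
#' @return character vector
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Module score (density times size)
#' @param x an [MCODEComplex-class]
#' @return numeric(1)
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' Bottleneck-hub symbols of a selection
#' @param x a [RankedSelection-class]
#' @return character vector
#' @export
setGeneric("bottleneckHubs", function(x) standardGeneric("bottleneckHubs"))

setMethod("numNodes", "ConsensusNetwork",
    function(x) igraph::vcount(x@graph))
setMethod("numNodes", "igraph", function(x) igraph::vcount(x))
setMethod("numEdges", "ConsensusNetwork",
    function(x) igraph::ecount(x@graph))
setMethod("numEdges", "igraph", function(x) igraph::ecount(x))
setMethod("networkNodes", "ConsensusNetwork",
    function(x) igraph::V(x@graph)$name)
setMethod("networkNodes", "igraph", function(x) igraph::V(x)$name)

setMethod("networkEdges", "ConsensusNetwork", function(x) {
    el <- igraph::as_edgelist(x@graph)
    df <- data.frame(geneA = el[, 1], geneB = el[, 2],
                     stringsAsFactors = FALSE)
    if (nrow(df) > 0) df$support <- igraph::E(x@graph)$support
    df
})

setMethod("edgeSupport", "ConsensusNetwork",
    function(x) as.integer(igraph::E(x@graph)$support))
setMethod("asIgraph", "ConsensusNetwork", function(x) x@graph)

setMethod("members", "MCODEComplex", function(x) x@members)
setMethod("moduleScore", "MCODEComplex", function(x) x@score)
setMethod("bottleneckHubs", "RankedSelection", function(x) x@bottleneckHubs)

setMethod("show", "ConsensusNetwork", function(object) {
    cat("ConsensusNetwork with", numNodes(object), "nodes and",
        numEdges(object), "edges\n")
    cat("  minimum source support:", object@minSources, "\n")
    if (numEdges(object) > 0) {
        supp <- edgeSupport(object)
        cat("  support range: [", min(supp), ", ", max(supp), "]\n", sep = "")
    }
})

setMethod("show", "DegreeCurve", function(object) {
    cat("DegreeCurve \"", object@statistic, "\": ",
        length(object@degrees), " degree points", sep = "")
    if (length(object@degrees))
        cat(" (k in [", min(object@degrees), ", ", max(object@degrees), "])",
            sep = "")
    cat("\n")
})

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf(
        "PowerLawFit of %s: exponent %.4f (stderr %.4f), r = %.4f, %d points, k in [%d, %d]\n",
        object@statistic, object@exponent, object@stderr, object@r,
        object@nPoints, object@fitRange[1], object@fitRange[2]))
})

setMethod("show", "RankedSelection", function(object) {
    cat("RankedSelection: top", object@count, "per metric")
    if (!is.na(object@fraction))
        cat(sprintf(" (fraction %.3g)", object@fraction))
    cat("\n  bottleneck-hubs:", length(object@bottleneckHubs),
        "\n  hub-only:", length(object@hubOnly),
        "\n  bottleneck-only:", length(object@bottleneckOnly), "\n")
})

setMethod("show", "KnockoutResult", function(object) {
    cat(sprintf(
        "KnockoutResult '%s': %d edges removed, components %+d, mean|dCB| %.4g, max|dCB| %.4g\n",
        object@removed, object@edgesRemoved, object@nComponentsDelta,
        object@meanAbsDeltaCB, object@maxAbsDeltaCB))
})

setMethod("show", "MCODEComplex", function(object) {
    cat(sprintf(
        "MCODEComplex (seed %s): %d nodes, %d edges, density %.3f, score %s\n",
        object@seed, object@nNodes, object@nEdges, object@density,
        formatScore(object@score)))
})

setMethod("show", "MCODEParams", function(object) {
    cat("MCODEParams: node score cutoff", object@nodeScoreCutoff,
        "| haircut", object@haircut, "| fluff", object@fluff,
        "(cutoff", paste0(object@fluffDensityCutoff, ")"),
        "| k-core", object@kCore, "| max depth", object@maxDepth,
        "| min score", object@minScore, "\n")
})

setMethod("show", "CrosstalkMatrix", function(object) {
    cat("CrosstalkMatrix:", nrow(object@counts), "bottleneck-hubs x",
        ncol(object@counts), "modules\n")
    if (nrow(object@counts)) {
        top <- rownames(object@counts)[1]
        cat("  strongest row:", top, "(total", object@totals[1], ")\n")
    }
})

setMethod("show", "TermCollection", function(object) {
    cat("TermCollection [", object@namespace, "]: ", length(object@ids),
        " terms, set sizes ", sep = "")
    if (length(object@ids))
        cat(min(lengths(object@genes)), "-", max(lengths(object@genes)),
            sep = "")
    cat("\n")
})

setMethod("show", "DiseaseClassProfile", function(object) {
    cat("DiseaseClassProfile:", length(unique(object@perGene$gene)),
        "genes,", nrow(object@module), "module-level classes\n")
})
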