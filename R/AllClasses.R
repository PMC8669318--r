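#' @import methods
#' @importFrom stats coef cor lm phyper p.adjust runif sd setNames
#' @importFrom utils combn head read.delim write.table
NULL

setOldClass("igraph")

#' ConsensusNetwork: a multi-source consensus interaction network
#'
#' An undirected simple graph whose edges are interactions supported by at
#' least \code{minSources} distinct source databases.  Nodes are canonical
#' gene symbols; every edge carries its source-support count.
#'
#' @slot graph an \pkg{igraph} object (undirected, simple) with vertex
#'   attribute \code{name} and edge attribute \code{support}.
#' @slot minSources integer(1), the minimum source support every edge meets.
#'
#' @seealso [buildConsensus()], [consensusNetwork()], [writeConsensus()]
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
    representation(graph = "igraph", minSources = "integer"))

setValidity("ConsensusNetwork", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g))
        msg <- c(msg, "graph must not contain self-loops")
    if (igraph::any_multiple(g))
        msg <- c(msg, "graph must not contain duplicate edges")
    if (is.null(igraph::V(g)$name))
        msg <- c(msg, "vertices must be named")
    supp <- igraph::E(g)$support
    if (igraph::ecount(g) > 0) {
        if (is.null(supp))
            msg <- c(msg, "edges must carry a 'support' attribute")
        else if (any(supp < object@minSources))
            msg <- c(msg, "every edge support must be >= minSources")
    }
    if (length(object@minSources) != 1L || object@minSources < 1L)
        msg <- c(msg, "minSources must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' DegreeCurve: a statistic averaged (or summed) per degree value
#'
#' Holds one point per degree present in the network: either the degree
#' distribution P(k) or the per-degree mean of a node statistic, ready for
#' log-log power-law fitting.
#'
#' @slot degrees strictly increasing integer degrees.
#' @slot values the statistic at each degree.
#' @slot counts number of nodes contributing to each point (may be empty
#'   when unknown).
#' @slot statistic label, e.g. "P(k)", "clustering", "betweenness".
#'
#' @exportClass DegreeCurve
setClass("DegreeCurve",
    representation(degrees = "integer", values = "numeric",
                   counts = "integer", statistic = "character"),
    prototype(counts = integer()))

setValidity("DegreeCurve", function(object) {
    msg <- character()
    if (length(object@degrees) != length(object@values))
        msg <- c(msg, "degrees and values must have equal length")
    if (length(object@counts) &&
        length(object@counts) != length(object@degrees))
        msg <- c(msg, "counts, when given, must align with degrees")
    if (is.unsorted(object@degrees, strictly = TRUE))
        msg <- c(msg, "degrees must be strictly increasing")
    if (identical(object@statistic, "P(k)") && length(object@values) &&
        abs(sum(object@values) - 1) > 1e-12)
        msg <- c(msg, "P(k) values must sum to 1")
    if (length(msg)) msg else TRUE
})

#' PowerLawFit: least-squares power-law fit of a degree curve
#'
#' Result of ordinary least squares of log10(value) on log10(degree); the
#' exponent is reported as the positive decay exponent (minus the fitted
#' slope).
#'
#' @slot exponent fitted decay exponent (-slope on log-log axes).
#' @slot stderr standard error of the slope.
#' @slot r Pearson correlation of log10(value) against log10(degree).
#' @slot nPoints number of points entering the fit.
#' @slot fitRange integer(2), smallest and largest degree used.
#' @slot statistic label of the fitted curve.
#'
#' @exportClass PowerLawFit
setClass("PowerLawFit",
    representation(exponent = "numeric", stderr = "numeric", r = "numeric",
                   nPoints = "integer", fitRange = "integer",
                   statistic = "character"))

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
        msg <- c(msg, "|r| must be <= 1")
    if (object@nPoints < 3L)
        msg <- c(msg, "nPoints must be >= 3")
    if (!is.na(object@stderr) && object@stderr < 0)
        msg <- c(msg, "stderr must be >= 0")
    if (length(msg)) msg else TRUE
})

#' RankedSelection: hubs, bottlenecks and their intersection
#'
#' Nodes in the top fraction by degree (hubs) and by betweenness
#' (bottlenecks), with the bottleneck-hub intersection and the two set
#' differences.
#'
#' @slot fraction the top fraction q used for selection (NA when lists were
#'   supplied directly).
#' @slot count number of nodes selected per metric, floor(q * N).
#' @slot hubs ordered hub symbols (degree descending).
#' @slot bottlenecks ordered bottleneck symbols (betweenness descending).
#' @slot bottleneckHubs intersection of the two lists.
#' @slot hubOnly hubs that are not bottlenecks.
#' @slot bottleneckOnly bottlenecks that are not hubs.
#'
#' @exportClass RankedSelection
setClass("RankedSelection",
    representation(fraction = "numeric", count = "integer",
                   hubs = "character", bottlenecks = "character",
                   bottleneckHubs = "character", hubOnly = "character",
                   bottleneckOnly = "character"))

setValidity("RankedSelection", function(object) {
    msg <- character()
    if (length(object@hubs) != object@count ||
        length(object@bottlenecks) != object@count)
        msg <- c(msg, "hub and bottleneck lists must both have 'count' entries")
    if (!setequal(object@bottleneckHubs,
                  intersect(object@hubs, object@bottlenecks)))
        msg <- c(msg, "bottleneckHubs must equal the intersection")
    if (!setequal(union(object@hubOnly, object@bottleneckHubs), object@hubs))
        msg <- c(msg, "hubOnly and bottleneckHubs must partition the hubs")
    if (length(msg)) msg else TRUE
})

#' KnockoutResult: perturbation summary of a single-node knockout
#'
#' @slot removed the removed node symbol.
#' @slot nComponentsDelta change in connected-component count (after - before).
#' @slot edgesRemoved number of incident edges removed (the intact degree).
#' @slot meanAbsDeltaCB mean |change in betweenness| over surviving nodes.
#' @slot maxAbsDeltaCB max |change in betweenness| over surviving nodes.
#' @slot degreeCurveAfter [DegreeCurve-class] P(k) of the perturbed network.
#'
#' @exportClass KnockoutResult
setClass("KnockoutResult",
    representation(removed = "character", nComponentsDelta = "integer",
                   edgesRemoved = "integer", meanAbsDeltaCB = "numeric",
                   maxAbsDeltaCB = "numeric", degreeCurveAfter = "DegreeCurve"))

#' MCODEParams: parameters of the MCODE module-detection algorithm
#'
#' Defaults follow the standard tool: node score cutoff 0.2, haircut on,
#' fluff off with density cutoff 0.1, k-core filter 2, maximum expansion
#' depth 100, module score threshold 4.
#'
#' @slot nodeScoreCutoff numeric in [0,1]; a neighbor joins a complex when
#'   its weight exceeds seed weight times (1 - cutoff).
#' @slot haircut logical; iteratively trim members with < 2 internal
#'   neighbors.
#' @slot fluff logical; add boundary nodes with dense closed neighborhoods.
#' @slot fluffDensityCutoff numeric in [0,1].
#' @slot kCore integer >= 2; complexes lacking a k-core are discarded.
#' @slot maxDepth integer >= 1; breadth-first expansion radius from the seed.
#' @slot minScore modules must exceed this density-times-size score.
#'
#' @seealso [mcodeParams()], [mcode()]
#' @exportClass MCODEParams
setClass("MCODEParams",
    representation(nodeScoreCutoff = "numeric", haircut = "logical",
                   fluff = "logical", fluffDensityCutoff = "numeric",
                   kCore = "integer", maxDepth = "integer",
                   minScore = "numeric"))

setValidity("MCODEParams", function(object) {
    msg <- character()
    if (object@nodeScoreCutoff < 0 || object@nodeScoreCutoff > 1)
        msg <- c(msg, "nodeScoreCutoff must lie in [0,1]")
    if (object@fluffDensityCutoff < 0 || object@fluffDensityCutoff > 1)
        msg <- c(msg, "fluffDensityCutoff must lie in [0,1]")
    if (object@kCore < 2L) msg <- c(msg, "kCore must be >= 2")
    if (object@maxDepth < 1L) msg <- c(msg, "maxDepth must be >= 1")
    if (length(msg)) msg else TRUE
})

#' MCODEComplex: one predicted molecular complex
#'
#' @slot members node symbols in the complex.
#' @slot seed the seed node the complex was grown from.
#' @slot nNodes member count.
#' @slot nEdges internal edge count.
#' @slot density 2 * nEdges / (nNodes * (nNodes - 1)).
#' @slot score density times size (the M-score).
#'
#' @exportClass MCODEComplex
setClass("MCODEComplex",
    representation(members = "character", seed = "character",
                   nNodes = "integer", nEdges = "integer",
                   density = "numeric", score = "numeric"))

setValidity("MCODEComplex", function(object) {
    msg <- character()
    if (!object@seed %in% object@members)
        msg <- c(msg, "seed must be a member")
    if (object@nNodes != length(object@members))
        msg <- c(msg, "nNodes must equal the member count")
    if (object@nNodes >= 2 &&
        abs(object@score - object@density * object@nNodes) > 1e-12)
        msg <- c(msg, "score must equal density * nNodes")
    if (length(msg)) msg else TRUE
})

#' CrosstalkMatrix: bottleneck-hub by module interaction strengths
#'
#' Integer counts of consensus-network edges between each bottleneck-hub and
#' the members of each module (the hub itself excluded when it is a member),
#' with row totals and membership flags.
#'
#' @slot counts integer matrix, rows = bottleneck-hubs ordered by total
#'   descending, columns = modules.
#' @slot totals per-row sums.
#' @slot membership logical matrix, TRUE where the hub is a module member.
#'
#' @exportClass CrosstalkMatrix
setClass("CrosstalkMatrix",
    representation(counts = "matrix", totals = "integer",
                   membership = "matrix"))

setValidity("CrosstalkMatrix", function(object) {
    msg <- character()
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (!identical(unname(as.integer(rowSums(object@counts))),
                   unname(object@totals)))
        msg <- c(msg, "totals must equal exact row sums")
    if (!identical(dim(object@counts), dim(object@membership)))
        msg <- c(msg, "membership must match counts in shape")
    if (length(msg)) msg else TRUE
})

#' TermCollection: named gene sets for over-representation analysis
#'
#' @slot ids unique term identifiers.
#' @slot descriptions one per term.
#' @slot genes list of character vectors, one gene set per term.
#' @slot namespace collection label (e.g. "biological process").
#'
#' @seealso [readGMT()], [enrich()]
#' @exportClass TermCollection
setClass("TermCollection",
    representation(ids = "character", descriptions = "character",
                   genes = "list", namespace = "character"))

setValidity("TermCollection", function(object) {
    msg <- character()
    if (anyDuplicated(object@ids)) msg <- c(msg, "term ids must be unique")
    if (length(object@ids) != length(object@genes) ||
        length(object@ids) != length(object@descriptions))
        msg <- c(msg, "ids, descriptions and genes must align")
    if (any(lengths(object@genes) == 0))
        msg <- c(msg, "gene sets must be non-empty")
    if (length(msg)) msg else TRUE
})

#' DiseaseClassProfile: disease-class percentages per gene and per module
#'
#' For each gene (and for the module as a whole) the percentage of its
#' distinct associated diseases falling in each disease class.  A disease
#' tagged with several classes contributes to each, so percentages can sum
#' above 100.
#'
#' @slot perGene data.frame with columns gene, class, nDiseases, percentage.
#' @slot module data.frame with columns class, nDiseases, percentage computed
#'   over the union of the genes' disease associations.
#'
#' @seealso [diseaseClassProfile()]
#' @exportClass DiseaseClassProfile
setClass("DiseaseClassProfile",
    representation(perGene = "data.frame", module = "data.frame"))
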