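#' Read a seed gene list
#'
#' Reads one gene symbol per line, normalizes case (uppercase, whitespace
#' stripped), resolves aliases through an optional two-column alias map and
#' deduplicates while preserving first-seen order.  Alias chains are followed
#' to their canonical end; a cycle or an alias mapped to two different
#' canonical symbols is an error naming the offending alias.
#'
#' @param path text file, one symbol per line (blank lines ignored)
#' @param aliasPath optional two-column TSV (alias, canonical), no header
#' @return character vector of unique canonical symbols, with the alias map
#'   (as a named character vector) attached as attribute \code{aliasMap}
#' @examples
#' f <- tempfile(); writeLines(c("SOD1", "sod1", "FUS"), f)
#' readSeedGenes(f)
#' @export
readSeedGenes <- function(path, aliasPath = NULL) {
    raw <- readLines(path, warn = FALSE)
    syms <- toupper(trimws(raw))
    syms <- syms[nzchar(syms)]
    if (length(syms) == 0) stop("no seed genes in '", path, "'")

    aliasMap <- character()
    if (!is.null(aliasPath)) {
        am <- read.delim(aliasPath, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
        if (ncol(am) < 2) stop("alias map must have two columns")
        alias <- toupper(trimws(am[[1]]))
        canon <- toupper(trimws(am[[2]]))
        keep <- nzchar(alias) & nzchar(canon)
        alias <- alias[keep]; canon <- canon[keep]
        for (a in unique(alias[duplicated(alias)])) {
            tg <- unique(canon[alias == a])
            if (length(tg) > 1)
                stop("conflicting alias '", a, "' maps to: ",
                     paste(tg, collapse = ", "))
        }
        dedup <- !duplicated(alias)
        aliasMap <- setNames(canon[dedup], alias[dedup])
        syms <- vapply(syms, .resolveAlias, character(1), map = aliasMap,
                       USE.NAMES = FALSE)
    }
    out <- syms[!duplicated(syms)]
    attr(out, "aliasMap") <- aliasMap
    out
}

# follow alias chains to the canonical symbol; error on cycles
.resolveAlias <- function(sym, map) {
    seen <- character()
    while (sym %in% names(map)) {
        if (sym %in% seen)
            stop("alias cycle involving '", sym, "'")
        seen <- c(seen, sym)
        sym <- unname(map[[sym]])
    }
    sym
}

#' Read an interaction edge table from one source database
#'
#' Parses a per-source interaction export into interaction records.  Two
#' dialects are supported: \code{"tsv"} (two columns geneA, geneB; a header
#' line starting with "geneA" is skipped) and \code{"mitab-min"} (a minimal
#' PSI-MITAB 2.5 subset where columns 1 and 2 carry interactor identifiers
#' such as \code{uniprotkb:TP53}; the text after the last colon of the first
#' pipe-separated entry is taken as the gene symbol).  Pairs are unordered;
#' self-loop rows are retained here and removed by [buildConsensus()].
#' Malformed rows are skipped and counted in attribute \code{skipped}.
#'
#' @param path file to read
#' @param sourceId short label identifying the source database
#' @param dialect one of \code{"tsv"}, \code{"mitab-min"}
#' @return data.frame with columns geneA, geneB, source; attribute
#'   \code{skipped} holds the count of malformed rows
#' @export
readSourceEdges <- function(path, sourceId, dialect = c("tsv", "mitab-min")) {
    dialect <- match.arg(dialect)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!startsWith(lines, "#")]
    skipped <- 0L
    recA <- recB <- character()
    for (ln in lines) {
        fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (dialect == "tsv" && length(fields) >= 1 &&
            toupper(trimws(fields[1])) %in% c("GENEA", "GENE_A")) next
        if (length(fields) < 2) { skipped <- skipped + 1L; next }
        if (dialect == "tsv") {
            a <- toupper(trimws(fields[1])); b <- toupper(trimws(fields[2]))
        } else {
            a <- .mitabSymbol(fields[1]); b <- .mitabSymbol(fields[2])
        }
        if (!nzchar(a) || !nzchar(b)) { skipped <- skipped + 1L; next }
        recA <- c(recA, a); recB <- c(recB, b)
    }
    if (skipped > 0)
        message(skipped, " malformed row(s) skipped in '", path, "'")
    if (length(recA) == 0) stop("no parseable interaction rows in '", path, "'")
    out <- data.frame(geneA = recA, geneB = recB, source = sourceId,
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    out
}

# "uniprotkb:P04637|entrez:TP53" -> symbol from the first entry, text after
# the last colon, parenthetical qualifiers stripped
.mitabSymbol <- function(field) {
    entry <- strsplit(trimws(field), "|", fixed = TRUE)[[1]][1]
    if (is.na(entry) || !nzchar(entry)) return("")
    sym <- sub(".*:", "", entry)
    sym <- sub("\\(.*\\)$", "", sym)
    toupper(trimws(sym))
}

#' Build the consensus network from multi-source interaction records
#'
#' An unordered gene pair becomes an edge of the consensus network when it is
#' reported by at least \code{minSources} distinct source databases.
#' Duplicate records within a single source count once; self-loops are
#' removed before counting; nodes left without any surviving edge are
#' excluded.
#'
#' @param records data.frame with columns geneA, geneB, source — typically
#'   \code{rbind} of several [readSourceEdges()] results
#' @param minSources minimum number of distinct supporting sources (>= 1)
#' @return a [ConsensusNetwork-class]
#' @examples
#' rec <- data.frame(geneA = c("A", "A", "A"), geneB = c("B", "B", "C"),
#'                   source = c("S1", "S2", "S1"))
#' buildConsensus(rec, minSources = 2)
#' @export
buildConsensus <- function(records, minSources = 2L) {
    minSources <- as.integer(minSources)
    if (minSources < 1L) stop("minSources must be >= 1")
    if (NROW(records) == 0) stop("no interaction records supplied")
    a <- toupper(trimws(records$geneA))
    b <- toupper(trimws(records$geneB))
    src <- as.character(records$source)
    keep <- a != b                       # drop self-loops
    a <- a[keep]; b <- b[keep]; src <- src[keep]
    if (length(a) == 0) stop("empty consensus network")
    key <- .pairKey(a, b)
    # distinct sources per unordered pair
    dedup <- !duplicated(paste(key, src, sep = "\r"))
    supp <- table(key[dedup])
    edges <- names(supp)[supp >= minSources]
    if (length(edges) == 0) stop("empty consensus network")
    parts <- strsplit(edges, "|", fixed = TRUE)
    el <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::E(g)$support <- as.integer(supp[edges])
    new("ConsensusNetwork", graph = g, minSources = minSources)
}

#' Construct a ConsensusNetwork directly from an edge list
#'
#' Convenience constructor used for synthetic networks and for re-importing
#' written networks, where source evidence has already been collapsed.
#'
#' @param edges data.frame with columns geneA, geneB and optionally support
#' @param minSources declared minimum support of the edges (default 1)
#' @return a [ConsensusNetwork-class]
#' @export
consensusNetwork <- function(edges, minSources = 1L) {
    minSources <- as.integer(minSources)
    a <- toupper(trimws(as.character(edges$geneA)))
    b <- toupper(trimws(as.character(edges$geneB)))
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    supp <- if (!is.null(edges$support)) as.integer(edges$support)[keep]
            else rep(minSources, length(a))
    key <- .pairKey(a, b)
    first <- !duplicated(key)
    g <- igraph::graph_from_edgelist(cbind(pmin(a, b), pmax(a, b))[first, ,
                                                                   drop = FALSE],
                                     directed = FALSE)
    igraph::E(g)$support <- supp[first]
    new("ConsensusNetwork", graph = g, minSources = minSources)
}

#' Write a consensus network to disk
#'
#' @param net a [ConsensusNetwork-class]
#' @param path output file
#' @param format \code{"tsv"} (geneA, geneB, support; tab-separated, with
#'   header) or \code{"graphml"}
#' @return invisibly, \code{path}
#' @export
writeConsensus <- function(net, path, format = c("tsv", "graphml")) {
    format <- match.arg(format)
    if (format == "tsv") {
        write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else {
        igraph::write_graph(asIgraph(net), path, format = "graphml")
    }
    invisible(path)
}

#' Read a consensus network written by [writeConsensus()]
#'
#' @param path file to read
#' @param format \code{"tsv"} or \code{"graphml"}
#' @param minSources declared minimum support (metadata only)
#' @return a [ConsensusNetwork-class]
#' @export
readConsensus <- function(path, format = c("tsv", "graphml"),
                          minSources = 1L) {
    format <- match.arg(format)
    if (format == "tsv") {
        df <- read.delim(path, stringsAsFactors = FALSE)
        consensusNetwork(df, minSources = minSources)
    } else {
        g <- igraph::read_graph(path, format = "graphml")
        g <- igraph::simplify(g, edge.attr.comb = list(support = "max"))
        if (is.null(igraph::E(g)$support))
            igraph::E(g)$support <- rep(as.integer(minSources),
                                        igraph::ecount(g))
        igraph::E(g)$support <- as.integer(igraph::E(g)$support)
        new("ConsensusNetwork", graph = g,
            minSources = as.integer(minSources))
    }
}
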