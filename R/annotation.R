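#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated fields term id,
#' description, then one or more genes.  Duplicate genes within a term are
#' collapsed; symbols are uppercased.
#'
#' @param path GMT file
#' @param namespace collection label attached to the result
#' @return a [TermCollection-class]
#' @export
readGMT <- function(path, namespace = "gene sets") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty GMT file '", path, "'")
    ids <- descs <- character(length(lines))
    genes <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(fields) < 3)
            stop("GMT line ", i, " has fewer than 3 fields")
        ids[i] <- fields[1]
        descs[i] <- fields[2]
        genes[[i]] <- unique(toupper(trimws(fields[-(1:2)])))
    }
    new("TermCollection", ids = ids, descriptions = descs, genes = genes,
        namespace = namespace)
}

#' Write a TermCollection as GMT
#'
#' @param terms a [TermCollection-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeGMT <- function(terms, path) {
    lines <- vapply(seq_along(terms@ids), function(i)
        paste(c(terms@ids[i], terms@descriptions[i], terms@genes[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Hypergeometric over-representation analysis of a gene set
#'
#' Tests every term of a collection for over-representation in a module
#' gene set.  Each term is first intersected with the universe; the p-value
#' is the hypergeometric upper tail P(X >= overlap) with the universe as
#' population, and Benjamini-Hochberg adjustment is applied across terms.
#'
#' @param moduleGenes character vector (must be contained in the universe)
#' @param terms a [TermCollection-class]
#' @param universe character vector, the annotation population — typically
#'   all nodes of the consensus network
#' @param alpha significance level on the adjusted p (default 0.05)
#' @return data.frame ordered by adjusted p ascending, with columns term,
#'   description, overlap, moduleSize, termSize, universeSize, p, pAdj,
#'   significant; attribute \code{adjustMethod} records "BH"
#' @examples
#' tc <- new("TermCollection", ids = "T1", descriptions = "toy",
#'           genes = list(c("A", "B", "C")), namespace = "demo")
#' enrich(c("A", "B"), tc, LETTERS[1:10])
#' @export
enrich <- function(moduleGenes, terms, universe, alpha = 0.05) {
    universe <- unique(toupper(universe))
    moduleGenes <- unique(toupper(moduleGenes))
    if (length(universe) == 0) stop("empty universe")
    if (length(moduleGenes) == 0) stop("empty module gene set")
    if (!all(moduleGenes %in% universe))
        stop("module genes outside the universe: ",
             paste(head(setdiff(moduleGenes, universe), 5), collapse = ", "))
    N <- length(universe)
    n <- length(moduleGenes)
    rows <- lapply(seq_along(terms@ids), function(i) {
        termGenes <- intersect(terms@genes[[i]], universe)
        K <- length(termGenes)
        x <- length(intersect(moduleGenes, termGenes))
        # upper tail P(X >= x); X ~ Hypergeom(N, K, n)
        p <- if (x == 0) 1 else phyper(x - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = terms@ids[i], description = terms@descriptions[i],
                   overlap = x, moduleSize = n, termSize = K,
                   universeSize = N, p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$pAdj <- p.adjust(out$p, method = "BH")
    out$significant <- out$pAdj <= alpha
    out <- out[order(out$pAdj, out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "adjustMethod") <- "BH"
    out
}

#' Read a gene-disease-class association table
#'
#' @param path TSV with columns gene, disease, class and optionally score;
#'   a header row is expected
#' @return data.frame with those columns, symbols uppercased
#' @export
readDiseaseTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("gene", "disease", "class")
    if (!all(need %in% names(df)))
        stop("disease table must have columns: ", paste(need, collapse = ", "))
    df$gene <- toupper(trimws(df$gene))
    df
}

#' Disease-class percentage profiles
#'
#' For each queried gene, the percentage of its distinct associated diseases
#' falling in each disease class (a disease tagged with several classes
#' contributes to each, so percentages may sum above 100).  The module-level
#' profile applies the same computation to the union of the genes'
#' disease associations.  An optional minimum association score filters the
#' records first.
#'
#' @param genes character vector of gene symbols to profile
#' @param records data.frame with columns gene, disease, class (and
#'   optionally score), as from [readDiseaseTable()]
#' @param minScore optional minimum value of the score column
#' @return a [DiseaseClassProfile-class]; genes without records trigger a
#'   warning and are absent from the per-gene table
#' @export
diseaseClassProfile <- function(genes, records, minScore = NULL) {
    genes <- unique(toupper(genes))
    if (!is.null(minScore)) {
        if (is.null(records$score))
            stop("minScore given but records have no score column")
        records <- records[records$score >= minScore, , drop = FALSE]
    }
    rec <- records[records$gene %in% genes, , drop = FALSE]
    if (nrow(rec) == 0)
        stop("no disease records for any of the queried genes")
    missing <- setdiff(genes, rec$gene)
    if (length(missing))
        warning("no disease records for: ", paste(missing, collapse = ", "))

    profileOf <- function(df) {
        totals <- length(unique(df$disease))
        cls <- unique(df[, c("disease", "class")])
        byClass <- table(cls$class)
        data.frame(class = names(byClass),
                   nDiseases = as.integer(byClass),
                   percentage = 100 * as.integer(byClass) / totals,
                   stringsAsFactors = FALSE, row.names = NULL)
    }
    perGene <- do.call(rbind, lapply(intersect(genes, unique(rec$gene)),
        function(gn) {
            pf <- profileOf(rec[rec$gene == gn, , drop = FALSE])
            cbind(gene = gn, pf, stringsAsFactors = FALSE)
        }))
    rownames(perGene) <- NULL
    new("DiseaseClassProfile", perGene = perGene, module = profileOf(rec))
}
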