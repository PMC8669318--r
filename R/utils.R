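# internal helpers shared across modules

# Accept either a ConsensusNetwork or a bare igraph everywhere downstream.
.asGraph <- function(net) {
    if (is(net, "ConsensusNetwork")) return(net@graph)
    if (igraph::is_igraph(net)) {
        if (is.null(igraph::V(net)$name))
            igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
        return(net)
    }
    stop("expected a ConsensusNetwork or igraph object")
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# canonical unordered-pair key "A|B" with A <= B
.pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Truncate a module score to two decimals for display
#'
#' Module scores are reported truncated (not rounded) to two decimal places,
#' the convention used for published M-scores: 4.375 displays as 4.37.
#' Full precision is retained in the [MCODEComplex-class] object itself.
#'
#' @param score numeric vector of scores
#' @return numeric vector truncated toward zero at the second decimal
#' @examples
#' truncateScore(c(8.8, 5.15, 4.6933, 4.375))
#' @export
truncateScore <- function(score) {
    trunc(score * 100 + 1e-9) / 100
}

#' @rdname truncateScore
#' @return `formatScore` returns the truncated score formatted as character.
#' @export
formatScore <- function(score) {
    formatC(truncateScore(score), format = "f", digits = 2)
}
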