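#' @include AllClasses.R
NULL

#' Derive a reproducible substream seed
#'
#' All randomness in a campaign flows from one master seed via named
#' substreams (design, gp, nmf, simulation, ...), so independent stages can
#' be re-run in isolation without disturbing each other's draws.
#'
#' @param seed master integer seed.
#' @param stream substream name.
#' @param index optional within-stream index (e.g. replicate number).
#' @return an integer in [0, 2^31).
#' @export
substreamSeed <- function(seed, stream, index = 0L) {
    h <- sum(utf8ToInt(as.character(stream)) *
             seq_along(utf8ToInt(as.character(stream))))
    as.integer((as.double(seed) * 48271 + h * 7919 + as.double(index) * 104729) %%
               2147483647)
}

## cosine similarity between two non-negative vectors; 0 if either is null
.cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
}

## key a composition vector for grouping (stable across reload from CSV)
.compositionKey <- function(x) paste(signif(as.numeric(x), 10), collapse = "|")

## half-up rounding to the nearest integer (R's round() is banker's)
.roundHalfUp <- function(x) floor(x + 0.5)

.assertScalarCount <- function(n, what = "n") {
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
        stop(what, " must be a positive integer")
    invisible(as.integer(n))
}
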