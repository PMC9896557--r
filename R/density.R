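#' @include AllClasses.R
NULL

#' Weighted kernel density of an archetype over process space
#'
#' Locates a product-distribution archetype in composition space: a
#' Gaussian-kernel density estimate of the experiment compositions,
#' weighted by that archetype's feature-matrix scores. Weights are
#' normalized to sum to 1; the diagonal bandwidth follows Scott's rule on
#' the weighted sample, `h_j = sigma_j * nEff^(-1/(d+4))`, with the
#' weighted standard deviation `sigma_j` and Kish's effective sample size
#' `nEff = 1 / sum(w_i^2)`. The returned density is normalized to
#' integrate to 1 over the (regular) grid.
#'
#' @param compositions n x d matrix of experiment compositions.
#' @param weights non-negative feature scores, at least one positive.
#' @param grid list of d regularly spaced axis vectors defining the
#'   evaluation grid.
#' @param bandwidth optional fixed per-dimension bandwidth overriding
#'   Scott's rule.
#' @return list: `grid` (the axes), `density` (array with
#'   `lengths(grid)` dimensions), `bandwidth`.
#' @export
archetypeDensity <- function(compositions, weights, grid, bandwidth = NULL) {
    X <- as.matrix(compositions)
    d <- ncol(X)
    weights <- as.numeric(weights)
    if (length(weights) != nrow(X))
        stop("one weight per composition required")
    if (any(weights < 0) || sum(weights) <= 0)
        stop("weights must be non-negative with at least one positive")
    if (!is.list(grid) || length(grid) != d)
        stop("grid must be a list of ", d, " axis vectors")
    w <- weights / sum(weights)

    if (is.null(bandwidth)) {
        nEff <- 1 / sum(w^2)
        mu <- colSums(X * w)
        sigma <- sqrt(pmax(colSums(sweep(X, 2L, mu)^2 * w), 1e-12))
        bandwidth <- sigma * nEff^(-1 / (d + 4))
    } else {
        bandwidth <- rep_len(as.numeric(bandwidth), d)
    }

    nodes <- as.matrix(expand.grid(grid))
    K <- matrix(1, nrow(nodes), nrow(X))
    for (j in seq_len(d))
        K <- K * stats::dnorm(outer(nodes[, j], X[, j], "-") /
                              bandwidth[j]) / bandwidth[j]
    dens <- as.numeric(K %*% w)

    cellVol <- prod(vapply(grid, function(a)
        if (length(a) > 1L) a[2L] - a[1L] else 1, numeric(1)))
    tot <- sum(dens) * cellVol
    if (tot > 0) dens <- dens / tot
    list(grid = grid,
         density = array(dens, dim = lengths(grid)),
         bandwidth = bandwidth)
}

#' Write a density map as gridded CSV
#'
#' One row per grid node: the axis coordinates plus the density value.
#'
#' @param dens result of [archetypeDensity()].
#' @param path output file.
#' @param axisNames optional axis column names.
#' @return `path`, invisibly.
#' @export
writeDensityMap <- function(dens, path, axisNames = NULL) {
    nodes <- expand.grid(dens$grid)
    names(nodes) <- axisNames %||% paste0("x", seq_along(dens$grid))
    nodes$density <- as.numeric(dens$density)
    utils::write.csv(nodes, path, row.names = FALSE)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
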