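#' @include AllClasses.R
NULL

#' Map compositions to/from the unit hypercube
#'
#' All sampling and surrogate modelling happens on normalized coordinates;
#' these convert between real reagent amounts and the unit cube.
#'
#' @param space a [ProcessSpace-class].
#' @param X numeric matrix (rows = points) or vector (one point) in real
#'   units (`toUnitCube`) or unit-cube units (`fromUnitCube`).
#' @return a matrix of the same shape with dimension names as columns.
#' @export
toUnitCube <- function(space, X) {
    stopifnot(is(space, "ProcessSpace"))
    X <- .asPointMatrix(X, nDims(space))
    lo <- lowerBounds(space); up <- upperBounds(space)
    U <- sweep(sweep(X, 2L, lo, "-"), 2L, up - lo, "/")
    colnames(U) <- dimNames(space)
    U
}

#' @rdname toUnitCube
#' @export
fromUnitCube <- function(space, X) {
    stopifnot(is(space, "ProcessSpace"))
    U <- .asPointMatrix(X, nDims(space))
    lo <- lowerBounds(space); up <- upperBounds(space)
    X <- sweep(sweep(U, 2L, up - lo, "*"), 2L, lo, "+")
    colnames(X) <- dimNames(space)
    X
}

.asPointMatrix <- function(X, d) {
    if (is.null(dim(X))) X <- matrix(X, ncol = d)
    if (ncol(X) != d) stop("points have wrong dimensionality")
    as.matrix(X)
}

## snap real-unit coordinates to each dimension's grid, where defined
.snapToGrid <- function(space, X) {
    d <- space@dimensions
    for (j in seq_len(nrow(d))) {
        if (!is.na(d$step[j])) {
            X[, j] <- d$lower[j] +
                .roundHalfUp((X[, j] - d$lower[j]) / d$step[j]) * d$step[j]
            X[, j] <- pmin(pmax(X[, j], d$lower[j]), d$upper[j])
        }
    }
    X
}

.gridCapacity <- function(space) {
    d <- space@dimensions
    if (all(is.na(d$step))) return(Inf)
    lev <- ifelse(is.na(d$step), Inf,
                  floor((d$upper - d$lower) / d$step) + 1)
    prod(lev)
}

#' Latin hypercube design over a process space
#'
#' Space-filling initial design: `n` points such that, for every
#' dimension, exactly one point falls in each of the `n` equal-width bins
#' of that dimension's range. Used for the first iteration of an
#' exploration, before any surrogate model exists.
#'
#' @param space a [ProcessSpace-class].
#' @param n number of compositions (default 48, one iteration's batch).
#' @param seed integer seed; fixed seed gives an identical design.
#' @return `n` x d matrix of compositions in real units.
#' @export
lhsDesign <- function(space, n = 48L, seed = 1L) {
    stopifnot(is(space, "ProcessSpace"))
    n <- .assertScalarCount(n)
    if (n > .gridCapacity(space))
        stop("n exceeds the capacity of the discretization grid")
    set.seed(seed)
    U <- lhs::randomLHS(n, nDims(space))
    .snapToGrid(space, fromUnitCube(space, U))
}

#' Uniform random design over a process space
#'
#' The random-sampling baseline: `n` i.i.d. uniform points within bounds.
#'
#' @inheritParams lhsDesign
#' @return `n` x d matrix of compositions in real units.
#' @export
randomDesign <- function(space, n = 48L, seed = 1L) {
    stopifnot(is(space, "ProcessSpace"))
    n <- .assertScalarCount(n)
    if (n > .gridCapacity(space))
        stop("n exceeds the capacity of the discretization grid")
    set.seed(seed)
    U <- matrix(stats::runif(n * nDims(space)), nrow = n)
    .snapToGrid(space, fromUnitCube(space, U))
}

#' Write a dispense table
#'
#' Exports a batch of suggested compositions as a CSV dispense table, one
#' row per composition and one column per reagent.
#'
#' @param X composition matrix (columns named by reagent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDispenseTable <- function(X, path) {
    utils::write.csv(as.data.frame(X), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a process space from a YAML or JSON config
#'
#' The config must contain a `dimensions` list, each entry with `name`,
#' `lower`, `upper` and optional `step`.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a [ProcessSpace-class].
#' @export
readProcessSpace <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    dims <- cfg$dimensions
    if (is.data.frame(dims)) {
        if (is.null(dims$step)) dims$step <- NA_real_
        return(ProcessSpace(dims$name, dims$lower, dims$upper, dims$step))
    }
    ProcessSpace(
        vapply(dims, `[[`, "", "name"),
        vapply(dims, function(d) as.numeric(d$lower), numeric(1)),
        vapply(dims, function(d) as.numeric(d$upper), numeric(1)),
        vapply(dims, function(d)
            if (is.null(d$step)) NA_real_ else as.numeric(d$step), numeric(1)))
}
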