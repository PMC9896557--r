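#' @include AllClasses.R
NULL

.JITTER <- 1e-8

## anisotropic scaled Euclidean distance matrix between row sets
.scaledDist <- function(X1, X2, ls) {
    X1s <- sweep(X1, 2L, ls, "/")
    X2s <- sweep(X2, 2L, ls, "/")
    d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
    sqrt(pmax(d2, 0))
}

#' Matern-5/2 covariance between two point sets
#'
#' `k(r) = s2 (1 + sqrt(5) r + 5 r^2 / 3) exp(-sqrt(5) r)` with `r` the
#' anisotropically scaled Euclidean distance. Twice-differentiable sample
#' paths: smooth enough for a response surface, rougher than a squared
#' exponential - the standard workhorse for experimental landscapes.
#'
#' @param X1,X2 point matrices (rows = points, unit-cube coordinates).
#' @param lengthScales per-dimension length scales (> 0).
#' @param signalVar signal variance s2.
#' @return covariance matrix `nrow(X1)` x `nrow(X2)`.
#' @export
matern52Kernel <- function(X1, X2, lengthScales, signalVar = 1) {
    r <- .scaledDist(as.matrix(X1), as.matrix(X2), lengthScales)
    s5r <- sqrt(5) * r
    signalVar * (1 + s5r + 5 * r^2 / 3) * exp(-s5r)
}

## negative log marginal likelihood at theta = log(c(ls, signalVar, noiseVar))
.gpNegLogLik <- function(theta, X, yc) {
    d <- ncol(X)
    ls <- exp(theta[seq_len(d)])
    sv <- exp(theta[d + 1L]); nv <- exp(theta[d + 2L])
    K <- matern52Kernel(X, X, ls, sv)
    diag(K) <- diag(K) + nv + .JITTER
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
    as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(L))) +
               0.5 * length(yc) * log(2 * pi))
}

#' Fit the Gaussian-process surrogate of the novelty landscape
#'
#' Fits a GP with a combined anisotropic Matern-5/2 and white-noise kernel
#' to (composition, novelty score) pairs by maximizing the log marginal
#' likelihood (type-II ML) with multi-start L-BFGS-B on log-parameters. A
#' constant mean equal to `mean(y)` is used; predictions revert to it far
#' from data.
#'
#' @param X compositions, rows normalized to the unit hypercube.
#' @param y novelty scores, one per row of X.
#' @param nRestarts optimizer restarts (default 8); the first start is a
#'   moderate default, the rest are seeded random draws.
#' @param seed integer seed for the restart draws.
#' @return a [GPSurrogate-class].
#' @export
fitSurrogate <- function(X, y, nRestarts = 8L, seed = 1L) {
    X <- as.matrix(X); y <- as.numeric(y)
    if (nrow(X) != length(y)) stop("X and y sizes differ")
    if (length(y) < 2L) stop("at least two observations required")
    d <- ncol(X)
    yc <- y - mean(y)
    lower <- c(rep(log(0.02), d), log(1e-6), log(1e-8))
    upper <- c(rep(log(20), d), log(1e2), log(1))
    sv0 <- max(stats::var(yc), 1e-4)
    base <- c(rep(log(0.3), d), log(sv0), log(sv0 / 10))
    set.seed(seed)
    starts <- list(base)
    for (i in seq_len(max(0L, nRestarts - 1L)))
        starts[[i + 1L]] <- pmin(pmax(base + stats::rnorm(d + 2L, 0, 1.2),
                                      lower), upper)
    best <- NULL
    for (th0 in starts) {
        fit <- tryCatch(
            stats::optim(th0, .gpNegLogLik, X = X, yc = yc,
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = 200)),
            error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
            best <- fit
    }
    if (is.null(best)) stop("marginal-likelihood optimization failed")
    th <- best$par
    ls <- exp(th[seq_len(d)]); sv <- exp(th[d + 1L]); nv <- exp(th[d + 2L])
    K <- matern52Kernel(X, X, ls, sv)
    diag(K) <- diag(K) + nv + .JITTER
    L <- chol(K)
    alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
    new("GPSurrogate", X = X, y = y,
        params = list(lengthScales = ls, signalVar = sv, noiseVar = nv),
        meanY = mean(y), L = L, alpha = as.numeric(alpha),
        logLik = -best$value)
}

#' GP posterior mean and standard deviation
#'
#' Closed-form posterior of the latent novelty function at new points.
#' The reported variance is that of the latent function (it excludes the
#' white-noise observation variance) and is clamped at zero.
#'
#' @param model a [GPSurrogate-class].
#' @param Xnew matrix of query points (unit-cube rows) or a single point.
#' @return list with numeric vectors `mean` and `sd`.
#' @export
predictSurrogate <- function(model, Xnew) {
    stopifnot(is(model, "GPSurrogate"))
    Xnew <- .asPointMatrix(Xnew, ncol(model@X))
    p <- model@params
    Ks <- matern52Kernel(Xnew, model@X, p$lengthScales, p$signalVar)
    mu <- model@meanY + as.numeric(Ks %*% model@alpha)
    v <- backsolve(model@L, t(Ks), transpose = TRUE)
    var <- pmax(p$signalVar - colSums(v^2), 0)
    list(mean = mu, sd = sqrt(var))
}

#' Confidence-bound acquisition value
#'
#' `mean(x) + kappa * sd(x)` in the direction of higher novelty (the
#' maximizing form of the confidence-bound family; `direction = "min"`
#' gives the literal lower bound `mean - kappa * sd` for minimization
#' formulations). `kappa = 0` degrades to pure exploitation of the
#' posterior mean; larger `kappa` rewards uncertain regions.
#'
#' @param model a [GPSurrogate-class].
#' @param x query point(s), unit-cube coordinates.
#' @param kappa non-negative exploration weight.
#' @param direction `"max"` (default) or `"min"`.
#' @return acquisition value(s).
#' @export
acquisitionValue <- function(model, x, kappa = 2, direction = c("max", "min")) {
    direction <- match.arg(direction)
    if (kappa < 0) stop("kappa must be non-negative")
    p <- predictSurrogate(model, x)
    if (direction == "max") p$mean + kappa * p$sd else p$mean - kappa * p$sd
}

## posterior under fixed hyperparameters for an augmented training set
## (used by the constant-liar batch loop; no refitting)
.gpPosteriorFixed <- function(X, y, params, meanY, Xnew) {
    K <- matern52Kernel(X, X, params$lengthScales, params$signalVar)
    diag(K) <- diag(K) + params$noiseVar + .JITTER
    L <- chol(K)
    alpha <- backsolve(L, backsolve(L, y - meanY, transpose = TRUE))
    Ks <- matern52Kernel(Xnew, X, params$lengthScales, params$signalVar)
    mu <- meanY + as.numeric(Ks %*% alpha)
    v <- backsolve(L, t(Ks), transpose = TRUE)
    list(mean = mu, sd = sqrt(pmax(params$signalVar - colSums(v^2), 0)))
}

## maximize the acquisition over the unit cube by multi-start L-BFGS-B
.maximizeAcquisition <- function(acqFun, d, nStarts, seed, extraStarts = NULL) {
    set.seed(seed)
    starts <- matrix(stats::runif(nStarts * d), ncol = d)
    if (!is.null(extraStarts)) starts <- rbind(starts, extraStarts)
    bestX <- NULL; bestV <- -Inf
    for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
            stats::optim(starts[i, ], function(u) -acqFun(matrix(u, nrow = 1L)),
                         method = "L-BFGS-B", lower = rep(0, d),
                         upper = rep(1, d), control = list(maxit = 100)),
            error = function(e) NULL)
        if (!is.null(fit) && -fit$value > bestV) {
            bestV <- -fit$value; bestX <- fit$par
        }
    }
    list(x = bestX, value = bestV)
}

#' Suggest the next batch of compositions
#'
#' Sequential batch construction by constant-liar fantasy updates: the
#' acquisition (confidence bound toward high novelty) is maximized by
#' multi-start local search over the unit cube; each picked point is
#' temporarily assigned the minimum observed score (a pessimistic lie)
#' and the posterior is recomputed under fixed hyperparameters before the
#' next pick, which pushes subsequent picks away from already-chosen
#' locations. Deterministic for a fixed seed.
#'
#' @param model a fitted [GPSurrogate-class].
#' @param space the [ProcessSpace-class] (for denormalization and
#'   optional grid snapping).
#' @param batchSize number of compositions (default 48).
#' @param kappa exploration weight (default 2).
#' @param seed integer seed.
#' @param nStarts local-search starts per pick (default 8).
#' @return `batchSize` x d matrix of distinct compositions in real units.
#' @export
suggestBatch <- function(model, space, batchSize = 48L, kappa = 2,
                         seed = 1L, nStarts = 8L) {
    stopifnot(is(model, "GPSurrogate"), is(space, "ProcessSpace"))
    batchSize <- .assertScalarCount(batchSize, "batchSize")
    if (batchSize > .gridCapacity(space))
        stop("batchSize exceeds the capacity of the discretization grid")
    d <- ncol(model@X)
    lie <- min(model@y)
    Xa <- model@X; ya <- model@y
    picks <- matrix(NA_real_, nrow = batchSize, ncol = d)
    bestTrain <- model@X[which.max(model@y), , drop = FALSE]
    for (b in seq_len(batchSize)) {
        acq <- function(u) {
            p <- .gpPosteriorFixed(Xa, ya, model@params, model@meanY, u)
            p$mean + kappa * p$sd
        }
        res <- .maximizeAcquisition(acq, d, nStarts,
                                    substreamSeed(seed, "acq", b),
                                    extraStarts = bestTrain)
        x <- res$x
        ## enforce distinctness: nudge exact repeats with a seeded jitter
        tries <- 0L
        while (b > 1L &&
               min(sqrt(rowSums(sweep(picks[seq_len(b - 1L), , drop = FALSE],
                                      2L, x)^2))) < 1e-9 && tries < 20L) {
            set.seed(substreamSeed(seed, "jitter", b * 100L + tries))
            x <- pmin(pmax(x + stats::rnorm(d, 0, 0.02), 0), 1)
            tries <- tries + 1L
        }
        picks[b, ] <- x
        Xa <- rbind(Xa, x); ya <- c(ya, lie)
    }
    out <- .snapToGrid(space, fromUnitCube(space, picks))
    if (anyDuplicated(out))
        stop("could not produce distinct points on the discretization grid")
    out
}
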