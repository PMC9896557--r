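#' @include AllClasses.R
NULL

## NNDSVDa initialization (nonnegative double SVD, zeros filled with the
## matrix mean) - deterministic, well suited to multiplicative updates
.nndsvda <- function(A, k) {
    sv <- svd(A, nu = k, nv = k)
    W <- matrix(0, nrow(A), k); H <- matrix(0, k, ncol(A))
    W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
    H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
    for (j in seq_len(k)[-1L]) {
        u <- sv$u[, j]; v <- sv$v[, j]
        up <- pmax(u, 0); un <- pmax(-u, 0)
        vp <- pmax(v, 0); vn <- pmax(-v, 0)
        nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
        nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
        if (nup * nvp >= nun * nvn) {
            scale <- sqrt(sv$d[j] * nup * nvp)
            if (nup > 0) W[, j] <- scale * up / nup
            if (nvp > 0) H[j, ] <- scale * vp / nvp
        } else {
            scale <- sqrt(sv$d[j] * nun * nvn)
            if (nun > 0) W[, j] <- scale * un / nun
            if (nvn > 0) H[j, ] <- scale * vn / nvn
        }
    }
    avg <- mean(A)
    W[W <= 0] <- avg; H[H <= 0] <- avg
    list(W = W, H = H)
}

## Frobenius multiplicative updates (Lee-Seung) from a given init
.nmfMU <- function(A, W, H, maxIter = 300L, tol = 1e-5) {
    eps <- .Machine$double.eps
    errPrev <- Inf
    for (it in seq_len(maxIter)) {
        H <- H * (crossprod(W, A) / (crossprod(W) %*% H + eps))
        W <- W * (A %*% t(H) / (W %*% tcrossprod(H) + eps))
        if (it %% 10L == 0L || it == maxIter) {
            err <- sqrt(sum((A - W %*% H)^2))
            if (is.finite(errPrev) && errPrev - err < tol * max(errPrev, eps))
                break
            errPrev <- err
        }
    }
    list(W = W, H = H, err = sqrt(sum((A - W %*% H)^2)))
}

## best-of-restarts NMF: deterministic NNDSVDa start plus seeded uniform
## random restarts, keeping the lowest Frobenius error
.nmfFit <- function(A, k, seed = 1L, nRestarts = 5L, maxIter = 300L,
                    tol = 1e-5) {
    ## NNDSVD needs k within the SVD rank; beyond it fall back to random
    inits <- if (k <= min(dim(A))) list(.nndsvda(A, k)) else list()
    scale <- sqrt(mean(A) / k)
    nRand <- max(if (length(inits)) nRestarts - 1L else nRestarts, 0L)
    for (r in seq_len(nRand)) {
        set.seed(substreamSeed(seed, "nmf-init", r))
        inits[[length(inits) + 1L]] <- list(
            W = matrix(stats::runif(nrow(A) * k, 0, 2 * scale), nrow(A), k),
            H = matrix(stats::runif(k * ncol(A), 0, 2 * scale), k, ncol(A)))
    }
    best <- NULL
    for (ini in inits) {
        fit <- .nmfMU(A, ini$W, ini$H, maxIter, tol)
        if (is.null(best) || fit$err < best$err) best <- fit
    }
    best
}

#' Screen NMF ranks by reconstruction error
#'
#' Factorizes the barcode matrix at every rank from 2 up to the number of
#' experiments (or `maxRank`) and records the Frobenius reconstruction
#' error of the best factorization found, using a deterministic NNDSVD
#' initialization (optionally with seeded random restarts). The resulting
#' error curve feeds [selectRank()].
#'
#' @param B a [BarcodeMatrix-class] (or plain non-negative matrix).
#' @param seed integer seed for restarts.
#' @param maxRank upper end of the screened range (default: number of
#'   experiments).
#' @param nRestarts restarts per rank (default 1: the deterministic
#'   NNDSVD start; screening rarely needs more).
#' @param maxIter multiplicative-update iterations per fit.
#' @return named numeric vector: rank -> reconstruction error.
#' @export
screenRanks <- function(B, seed = 1L, maxRank = NULL, nRestarts = 1L,
                        maxIter = 200L) {
    A <- if (is(B, "BarcodeMatrix")) barcodes(B) else as.matrix(B)
    m <- nrow(A)
    if (m < 2L) stop("at least two experiments required")
    if (is.null(maxRank)) maxRank <- m
    ranks <- seq(2L, min(maxRank, m))
    errs <- vapply(ranks, function(k)
        .nmfFit(A, k, seed, nRestarts, maxIter)$err, numeric(1))
    stats::setNames(errs, ranks)
}

#' Select the NMF rank at the reconstruction-error plateau
#'
#' Scans ranks in ascending order and returns the rank at which the error
#' curve flattens - the onset of the plateau where reconstruction error
#' "becomes minimized". Each improvement is measured relative to the
#' error at the smallest screened rank (the curve's overall scale): the
#' first rank whose successor improves by less than `plateauTol` of that
#' scale is returned. If the curve never flattens, the argmin rank is
#' returned.
#'
#' Improvements are deliberately not normalized by the local error
#' `err[k-1]`: on binary barcodes every rank beyond the true structure
#' can still absorb isolated bit-flip noise, so local relative
#' improvements stay at several percent (and grow as the error shrinks)
#' all the way to the maximum rank, which would defeat any local
#' threshold. Against the curve's initial scale those late improvements
#' are negligible and the knee is stable.
#'
#' @param errors named numeric vector over a contiguous rank range, as
#'   returned by [screenRanks()].
#' @param plateauTol improvement tolerance as a fraction of the initial
#'   screened error (default 0.05).
#' @return the selected rank (integer).
#' @export
selectRank <- function(errors, plateauTol = 0.05) {
    ranks <- as.integer(names(errors))
    o <- order(ranks); ranks <- ranks[o]; errors <- as.numeric(errors)[o]
    if (any(diff(ranks) != 1L)) stop("errors must cover a contiguous rank range")
    if (length(ranks) == 1L) {
        warning("single rank supplied; returning it")
        return(ranks)
    }
    scale <- errors[1L]
    if (scale <= 0) return(ranks[1L])
    for (i in seq_len(length(ranks) - 1L)) {
        impr <- (errors[i] - errors[i + 1L]) / scale
        if (impr < plateauTol) return(ranks[i])
    }
    ranks[which.min(errors)]
}

#' Factorize a barcode matrix into archetypes
#'
#' Non-negative matrix factorization of the binary barcode matrix at rank
#' `k`, minimizing Frobenius error by multiplicative updates from an
#' NNDSVD initialization plus seeded random restarts (best kept). Rows of
#' the coefficient matrix are normalized to unit maximum, with the
#' feature matrix rescaled to compensate, so fingerprints from different
#' models are comparable.
#'
#' @param B a [BarcodeMatrix-class] (or plain non-negative matrix with
#'   dimnames).
#' @param k rank, `2 <= k <=` number of experiments.
#' @param seed integer seed.
#' @param nRestarts restarts (default 5).
#' @param maxIter multiplicative-update iterations per restart.
#' @param rankErrors optional error curve from [screenRanks()] to record
#'   in the model.
#' @return an [ArchetypeModel-class].
#' @export
factorize <- function(B, k, seed = 1L, nRestarts = 5L, maxIter = 300L,
                      rankErrors = NULL) {
    A <- if (is(B, "BarcodeMatrix")) barcodes(B) else as.matrix(B)
    k <- .assertScalarCount(k, "k")
    if (k < 2L || k > nrow(A)) stop("k must satisfy 2 <= k <= m")
    fit <- .nmfFit(A, k, seed, nRestarts, maxIter)
    W <- fit$W; H <- fit$H
    hmax <- apply(H, 1L, max)
    hmax[hmax == 0] <- 1
    H <- H / hmax
    W <- sweep(W, 2L, hmax, "*")
    rownames(W) <- rownames(A)
    colnames(W) <- paste0("A", seq_len(k))
    rownames(H) <- colnames(W)
    colnames(H) <- colnames(A)
    errs <- if (is.null(rankErrors))
        stats::setNames(fit$err, k)
    else {
        re <- rankErrors
        re[as.character(k)] <- fit$err
        re
    }
    new("ArchetypeModel", featureMatrix = W, coefficientMatrix = H,
        rank = as.integer(k), rankErrors = errs, seed = as.integer(seed))
}

#' Serialize an archetype model to JSON
#'
#' @param model an [ArchetypeModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeArchetypeModel <- function(model, path) {
    stopifnot(is(model, "ArchetypeModel"))
    jsonlite::write_json(list(
        rank = modelRank(model),
        seed = model@seed,
        rankErrors = as.list(rankErrors(model)),
        featureMatrix = featureMatrix(model),
        coefficientMatrix = coefficientMatrix(model),
        experiments = rownames(featureMatrix(model)),
        bins = colnames(coefficientMatrix(model))),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
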