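#' @include AllClasses.R
NULL

#' Build a binary barcode matrix from peak sets
#'
#' Converts per-experiment peak sets (by default the non-starting-material
#' "unique" peaks) into an m x n binary presence/absence matrix: columns
#' are the sorted union of bins across the in-scope experiments, entry
#' (i, j) is 1 iff experiment i contains bin j. Experiments contributing
#' no peaks keep an all-zero row; bins observed nowhere are dropped (every
#' column has at least one 1).
#'
#' @param peakSets named list of integer bin vectors, one per experiment
#'   (names become row names).
#' @param scope list recording the restriction used (e.g.
#'   `list(temperature = "solvothermal")`); metadata only.
#' @return a [BarcodeMatrix-class].
#' @export
buildBarcodeMatrix <- function(peakSets, scope = list()) {
    if (!is.list(peakSets) || length(peakSets) < 2L)
        stop("scope must contain at least two experiments")
    if (is.null(names(peakSets)))
        names(peakSets) <- paste0("exp", seq_along(peakSets))
    bins <- sort(unique(unlist(lapply(peakSets, as.integer))))
    m <- matrix(0L, nrow = length(peakSets), ncol = length(bins),
                dimnames = list(names(peakSets), as.character(bins)))
    for (i in seq_along(peakSets))
        m[i, as.character(unique(as.integer(peakSets[[i]])))] <- 1L
    new("BarcodeMatrix", matrix = m, scope = scope)
}

#' Dominant archetype per experiment
#'
#' For each experiment (row of the feature matrix), the archetype with
#' the largest contribution and its percentage share of the row sum (ties
#' broken toward the lowest archetype index). An all-zero feature row has
#' no defined dominant archetype and is flagged.
#'
#' @param model an [ArchetypeModel-class].
#' @return data.frame with columns `experiment`, `archetype` (index, NA
#'   if undefined), `sharePercent`, `undefined` (logical).
#' @export
dominantArchetype <- function(model) {
    stopifnot(is(model, "ArchetypeModel"))
    W <- featureMatrix(model)
    out <- data.frame(
        experiment = rownames(W),
        archetype = NA_integer_,
        sharePercent = NA_real_,
        undefined = FALSE,
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(W))) {
        rs <- sum(W[i, ])
        if (rs == 0) { out$undefined[i] <- TRUE; next }
        j <- which.max(W[i, ])  # which.max takes the first (lowest) index on ties
        out$archetype[i] <- j
        out$sharePercent[i] <- 100 * W[i, j] / rs
    }
    out
}

## extract a fingerprint matrix (rows = archetypes) with bin colnames from
## an ArchetypeModel or a plain matrix
.fingerprintMatrix <- function(x) {
    if (is(x, "ArchetypeModel")) return(coefficientMatrix(x))
    m <- as.matrix(x)
    if (is.null(colnames(m))) stop("fingerprint matrix needs bin colnames")
    m
}

#' Match archetypes between two models
#'
#' Pairs the archetypes (coefficient-matrix rows) of two models over the
#' union of their peak columns (missing columns zero-filled) by greedy
#' best-first cosine similarity; pairs at or above `simThreshold` count as
#' shared discoveries. Used to compare explorations (e.g. GPBO-directed
#' vs random) or to score recovery of planted ground-truth fingerprints.
#'
#' @param modelA,modelB [ArchetypeModel-class] objects or plain
#'   non-negative matrices (rows = archetypes) with bin colnames.
#' @param simThreshold cosine similarity needed to call a pair shared
#'   (default 0.8).
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive best
#'   assignment; feasible for the smaller side up to ~8 archetypes).
#' @return list: `sharedFraction` (shared pairs / max(kA, kB)),
#'   `pairing` data.frame (`archetypeA`, `archetypeB`, `similarity`,
#'   `shared`).
#' @export
matchArchetypes <- function(modelA, modelB, simThreshold = 0.8,
                            method = c("greedy", "optimal")) {
    method <- match.arg(method)
    Ha <- .fingerprintMatrix(modelA)
    Hb <- .fingerprintMatrix(modelB)
    bins <- sort(unique(c(colnames(Ha), colnames(Hb))))
    pad <- function(H) {
        M <- matrix(0, nrow(H), length(bins),
                    dimnames = list(rownames(H), bins))
        M[, colnames(H)] <- H
        M
    }
    A <- pad(Ha); B <- pad(Hb)
    ka <- nrow(A); kb <- nrow(B)
    S <- matrix(0, ka, kb)
    for (i in seq_len(ka)) for (j in seq_len(kb))
        S[i, j] <- .cosine(A[i, ], B[j, ])
    pairs <- data.frame(archetypeA = integer(), archetypeB = integer(),
                        similarity = numeric())
    if (method == "greedy") {
        Sw <- S
        for (step in seq_len(min(ka, kb))) {
            idx <- arrayInd(which.max(Sw), dim(Sw))
            i <- idx[1L]; j <- idx[2L]
            if (Sw[i, j] < 0) break
            pairs <- rbind(pairs, data.frame(archetypeA = i, archetypeB = j,
                                             similarity = S[i, j]))
            Sw[i, ] <- -1; Sw[, j] <- -1
        }
    } else {
        small <- min(ka, kb)
        if (small > 8L) stop("optimal matching supported up to 8 archetypes")
        perms <- .permutations(max(ka, kb))
        bestSum <- -Inf; bestPerm <- NULL
        for (p in perms) {
            sel <- p[seq_len(small)]
            tot <- if (ka <= kb) sum(S[cbind(seq_len(small), sel)])
                   else sum(S[cbind(sel, seq_len(small))])
            if (tot > bestSum) { bestSum <- tot; bestPerm <- sel }
        }
        for (r in seq_len(small)) {
            i <- if (ka <= kb) r else bestPerm[r]
            j <- if (ka <= kb) bestPerm[r] else r
            pairs <- rbind(pairs, data.frame(archetypeA = i, archetypeB = j,
                                             similarity = S[i, j]))
        }
    }
    pairs$shared <- pairs$similarity >= simThreshold
    o <- order(pairs$archetypeA)
    pairs <- pairs[o, , drop = FALSE]
    rownames(pairs) <- NULL
    list(sharedFraction = sum(pairs$shared) / max(ka, kb), pairing = pairs)
}

## all permutations of 1..n, built by inserting n into each slot
.permutations <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (sub in .permutations(n - 1L))
        for (pos in seq_len(n))
            out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    out
}

#' Export a barcode matrix as sparse triplets
#'
#' Writes three CSVs: `<stem>_triplets.csv` (row, col, value = 1),
#' `<stem>_rows.csv` (experiment ids) and `<stem>_cols.csv` (bin m/z).
#'
#' @param B a [BarcodeMatrix-class].
#' @param stem path stem for the three files.
#' @return the triplet path, invisibly.
#' @export
writeBarcodeMatrix <- function(B, stem) {
    stopifnot(is(B, "BarcodeMatrix"))
    m <- barcodes(B)
    idx <- which(m == 1L, arr.ind = TRUE)
    utils::write.csv(data.frame(row = idx[, 1L], col = idx[, 2L], value = 1L),
                     paste0(stem, "_triplets.csv"), row.names = FALSE)
    utils::write.csv(data.frame(experiment = rownames(m)),
                     paste0(stem, "_rows.csv"), row.names = FALSE)
    utils::write.csv(data.frame(mz = as.integer(colnames(m))),
                     paste0(stem, "_cols.csv"), row.names = FALSE)
    invisible(paste0(stem, "_triplets.csv"))
}
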