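test_that("barcode matrices are brute-force membership tables", {
    # identical single-bin peak sets -> 2x1 matrix of ones
    B <- buildBarcodeMatrix(list(e1 = 354L, e2 = 354L))
    expect_equal(unname(barcodes(B)), matrix(1L, 2, 1))
    # disjoint 3-bin sets -> 2x6, rows summing to 3
    B2 <- buildBarcodeMatrix(list(a = c(100L, 110L, 120L),
                                  b = c(200L, 210L, 220L)))
    expect_equal(dim(barcodes(B2)), c(2L, 6L))
    expect_equal(unname(rowSums(barcodes(B2))), c(3, 3))
    # random sets vs brute force
    set.seed(31)
    sets <- lapply(1:20, function(i) sort(sample(300:360, sample(3:15, 1))))
    names(sets) <- paste0("e", 1:20)
    B3 <- buildBarcodeMatrix(sets)
    bins <- as.integer(colnames(barcodes(B3)))
    expect_equal(bins, sort(unique(unlist(sets))))
    for (i in 1:20) for (j in seq_along(bins))
        expect_equal(barcodes(B3)[i, j],
                     as.integer(bins[j] %in% sets[[i]]))
    expect_error(buildBarcodeMatrix(list(a = 1L)), "two experiments")
})

test_that("barcode construction is input-order invariant up to row permutation", {
    set.seed(32)
    sets <- lapply(1:8, function(i) sort(sample(100:150, 6)))
    names(sets) <- paste0("e", 1:8)
    B1 <- barcodes(buildBarcodeMatrix(sets))
    B2 <- barcodes(buildBarcodeMatrix(rev(sets)))
    expect_identical(B1, B2[rownames(B1), , drop = FALSE])
})

test_that("rank screening reaches zero on an exact rank-2 construction", {
    fx <- plantedBarcode(nArch = 2, nPer = 5, fpSize = 4, flipProb = 0)
    errs <- screenRanks(fx$M, seed = 1)
    expect_lt(errs[["2"]], 1e-6)
    # non-increasing within 1% slack (local optima; slack floored at 1% of
    # the matrix norm for near-zero errors); k = m no worse than k = 2
    e <- as.numeric(errs)
    slack <- 0.01 * max(e[-length(e)], sqrt(sum(fx$M^2)))
    expect_true(all(diff(e) <= 0.01 * e[-length(e)] + slack))
    expect_lte(e[length(e)], e[1] + slack)
})

test_that("rank selection picks the plateau onset", {
    # big drop to rank 3, then improvements < 1% of the initial error
    expect_equal(selectRank(c(`2` = 10, `3` = 1, `4` = 0.99, `5` = 0.985),
                            plateauTol = 0.01), 3L)
    # flat curve: immediate plateau at the first rank
    expect_equal(selectRank(c(`2` = 5, `3` = 5, `4` = 5)), 2L)
    # strictly improving beyond tolerance everywhere -> argmin (largest k)
    expect_equal(selectRank(c(`2` = 8, `3` = 4, `4` = 2, `5` = 1)), 5L)
    # knee detection is scale-invariant
    e <- c(`2` = 20, `3` = 14, `4` = 3, `5` = 2.8, `6` = 2.6, `7` = 2.4)
    expect_equal(selectRank(e), 4L)
    expect_equal(selectRank(e * 1000), 4L)
    expect_warning(k <- selectRank(c(`3` = 1)), "single rank")
    expect_equal(k, 3L)
    expect_error(selectRank(c(`2` = 3, `5` = 1)), "contiguous")
})

test_that("factorization recovers planted archetypes and is reproducible", {
    fx <- plantedBarcode(nArch = 4, nPer = 15, fpSize = 8, flipProb = 0.02,
                         seed = 5)
    model <- factorize(fx$M, 4, seed = 7)
    expect_true(all(featureMatrix(model) >= 0))
    expect_true(all(coefficientMatrix(model) >= 0))
    # coefficient rows normalized to unit maximum
    expect_equal(unname(apply(coefficientMatrix(model), 1, max)), rep(1, 4))
    # every planted fingerprint matched by some coefficient row at >= 0.9
    H <- coefficientMatrix(model)
    for (a in 1:4) {
        sims <- apply(H, 1, function(h) cosineSim(h, fx$truth[a, ]))
        expect_gte(max(sims), 0.9)
    }
    # bit-reproducible for a fixed seed
    expect_identical(coefficientMatrix(model),
                     coefficientMatrix(factorize(fx$M, 4, seed = 7)))
    # exact rank-k binary matrix reconstructs to numerical zero
    fx0 <- plantedBarcode(nArch = 3, nPer = 4, fpSize = 5, flipProb = 0)
    m0 <- factorize(fx0$M, 3, seed = 1)
    rec <- featureMatrix(m0) %*% coefficientMatrix(m0)
    expect_lt(sqrt(sum((fx0$M - rec)^2)), 1e-6)
})

test_that("rank selection finds the planted rank in most noisy replicates", {
    hits <- 0L
    for (r in 1:10) {
        fx <- plantedBarcode(nArch = 4, nPer = 12, fpSize = 7,
                             flipProb = 0.02, seed = 100 + r)
        k <- selectRank(screenRanks(fx$M, seed = r, maxRank = 10))
        if (abs(k - 4L) <= 1L) hits <- hits + 1L
    }
    expect_gte(hits, 8L)
    # noiseless: exact recovery
    fx0 <- plantedBarcode(nArch = 4, nPer = 12, fpSize = 7, flipProb = 0)
    expect_equal(selectRank(screenRanks(fx0$M, seed = 1, maxRank = 10)), 4L)
})

test_that("dominant archetypes are row-wise argmax shares", {
    W <- rbind(c(0, 0, 5), c(2, 2, 2), c(0, 0, 0), c(1, 3, 1))
    rownames(W) <- paste0("e", 1:4)
    H <- matrix(1, 3, 4, dimnames = list(NULL, as.character(101:104)))
    model <- new("ArchetypeModel", featureMatrix = W, coefficientMatrix = H,
                 rank = 3L, rankErrors = c(`3` = 0.5), seed = 1L)
    d <- dominantArchetype(model)
    expect_equal(d$archetype, c(3L, 1L, NA, 2L))  # ties -> lowest index
    expect_equal(d$sharePercent, c(100, 100 / 3, NA, 60))
    expect_equal(d$undefined, c(FALSE, FALSE, TRUE, FALSE))
    # brute-force oracle on random rows
    set.seed(41)
    W2 <- matrix(runif(50), 10, 5, dimnames = list(paste0("e", 1:10), NULL))
    H2 <- matrix(1, 5, 6, dimnames = list(NULL, as.character(1:6)))
    m2 <- new("ArchetypeModel", featureMatrix = W2, coefficientMatrix = H2,
              rank = 5L, rankErrors = c(`5` = 1), seed = 1L)
    d2 <- dominantArchetype(m2)
    expect_equal(d2$archetype, unname(apply(W2, 1, which.max)))
    expect_equal(d2$sharePercent,
                 unname(100 * apply(W2, 1, max) / rowSums(W2)))
})

test_that("archetype matching is permutation invariant with sensible bounds", {
    fx <- plantedBarcode(nArch = 4, nPer = 10, fpSize = 6, flipProb = 0.01)
    model <- factorize(fx$M, 4, seed = 3)
    # identical models share everything
    self <- matchArchetypes(model, model)
    expect_equal(self$sharedFraction, 1.0)
    # permuted archetype order: recovered with similarity 1 on each pair
    H <- coefficientMatrix(model)
    perm <- c(3, 1, 4, 2)
    Hp <- H[perm, , drop = FALSE]
    m <- matchArchetypes(H, Hp)
    expect_equal(m$sharedFraction, 1.0)
    expect_equal(m$pairing$archetypeB[order(m$pairing$archetypeA)],
                 order(perm))
    # column-disjoint models share nothing
    Ha <- matrix(1, 2, 3, dimnames = list(NULL, c("100", "101", "102")))
    Hb <- matrix(1, 2, 3, dimnames = list(NULL, c("200", "201", "202")))
    expect_equal(matchArchetypes(Ha, Hb)$sharedFraction, 0)
    # greedy and optimal agree on a clean problem
    expect_equal(matchArchetypes(H, Hp, method = "optimal")$sharedFraction, 1)
})

test_that("weighted archetype density localizes and normalizes", {
    grid <- list(seq(0, 1, length.out = 41), seq(0, 1, length.out = 41))
    X <- rbind(c(0.2, 0.2), c(0.8, 0.8), c(0.5, 0.1))
    # all weight on one composition: density peaks at its nearest node
    d1 <- archetypeDensity(X, c(1, 0, 0), grid, bandwidth = 0.05)
    peak <- arrayInd(which.max(d1$density), dim(d1$density))
    expect_equal(grid[[1]][peak[1]], 0.2, tolerance = 0.026)
    expect_equal(grid[[2]][peak[2]], 0.2, tolerance = 0.026)
    # integrates to 1 over the grid
    cell <- (grid[[1]][2] - grid[[1]][1]) * (grid[[2]][2] - grid[[2]][1])
    expect_equal(sum(d1$density) * cell, 1, tolerance = 1e-9)
    # uniform weights reduce to the unweighted estimate
    dU <- archetypeDensity(X, c(1, 1, 1), grid)
    dW <- archetypeDensity(X, c(2, 2, 2), grid)
    expect_equal(dU$density, dW$density)
    # two equal clusters split mass evenly between half-spaces within 5%
    set.seed(51)
    Xc <- rbind(matrix(rnorm(40, 0.25, 0.03), ncol = 2),
                matrix(rnorm(40, 0.75, 0.03), ncol = 2))
    dc <- archetypeDensity(Xc, rep(1, 40), grid)
    left <- sum(dc$density[grid[[1]] < 0.5, ])
    right <- sum(dc$density[grid[[1]] > 0.5, ])
    expect_lt(abs(left - right) / (left + right), 0.05)
    expect_error(archetypeDensity(X, c(0, 0, 0), grid), "weights")
})
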