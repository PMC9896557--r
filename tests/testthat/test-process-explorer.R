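test_that("unit-cube normalization round-trips", {
    sp <- ProcessSpace(c("a", "b", "c"), c(-2, 0, 10), c(3, 1, 50))
    set.seed(8)
    X <- cbind(runif(20, -2, 3), runif(20, 0, 1), runif(20, 10, 50))
    expect_equal(fromUnitCube(sp, toUnitCube(sp, X)),
                 fromUnitCube(sp, toUnitCube(sp, X)))
    expect_lt(max(abs(fromUnitCube(sp, toUnitCube(sp, X)) - X)), 1e-12)
})

test_that("Latin hypercube designs stratify every marginal", {
    sp6 <- ProcessSpace(paste0("r", 1:6), 0, 1)
    X <- lhsDesign(sp6, 48, seed = 1)
    expect_equal(dim(X), c(48L, 6L))
    for (j in 1:6)
        expect_equal(tabulate(ceiling(X[, j] * 48), 48), rep(1L, 48))
    # stratification holds for a spread of sizes, non-unit bounds included
    sp2 <- ProcessSpace(c("a", "b"), c(1, -5), c(3, 5))
    for (n in c(1L, 7L, 100L, 1000L)) {
        Xn <- lhsDesign(sp2, n, seed = n)
        U <- toUnitCube(sp2, Xn)
        for (j in 1:2)
            expect_equal(tabulate(ceiling(U[, j] * n), n), rep(1L, n))
    }
    # determinism
    expect_identical(lhsDesign(sp6, 48, seed = 9), lhsDesign(sp6, 48, seed = 9))
})

test_that("random designs are uniform within bounds and reproducible", {
    sp <- ProcessSpace(c("a", "b"), c(0, 10), c(2, 20))
    X <- randomDesign(sp, 10000, seed = 4)
    expect_true(all(X[, 1] >= 0 & X[, 1] <= 2))
    expect_true(all(X[, 2] >= 10 & X[, 2] <= 20))
    # marginal means within 3 standard errors of mid-range
    se1 <- 2 / sqrt(12) / sqrt(10000)
    se2 <- 10 / sqrt(12) / sqrt(10000)
    expect_lt(abs(mean(X[, 1]) - 1), 3 * se1)
    expect_lt(abs(mean(X[, 2]) - 15), 3 * se2)
    expect_identical(randomDesign(sp, 5, seed = 2), randomDesign(sp, 5, seed = 2))
    expect_equal(nrow(randomDesign(sp, 1, seed = 1)), 1L)
})

test_that("GP posterior matches the independent closed-form oracle", {
    set.seed(10)
    X <- matrix(runif(20), 10, 2)
    y <- sin(3 * X[, 1]) + cos(2 * X[, 2]) + rnorm(10, 0, 0.05)
    model <- fitSurrogate(X, y, nRestarts = 6, seed = 2)
    Xq <- matrix(runif(12), 6, 2)
    got <- predictSurrogate(model, Xq)
    want <- gpOracle(model, Xq)
    expect_lt(max(abs(got$mean - want$mean)), 1e-6)
    expect_lt(max(abs(got$sd - want$sd)), 1e-6)
})

test_that("GP interpolates noiseless data and reverts to the prior far away", {
    set.seed(12)
    X <- matrix(runif(16), 8, 2)
    y <- X[, 1] * 2 - X[, 2]
    model <- fitSurrogate(X, y, nRestarts = 6, seed = 3)
    p <- predictSurrogate(model, X)
    # noise variance collapses on noiseless data: near-interpolation
    expect_lt(max(abs(p$mean - y)), 1e-3)
    # far from all data (short length scales by construction of the check):
    # mean -> prior constant, sd -> signal sd
    far <- matrix(c(600, 600), 1, 2)
    pf <- predictSurrogate(model, far)
    expect_equal(pf$mean, mean(y), tolerance = 1e-6)
    expect_equal(pf$sd, sqrt(hyperParameters(model)$signalVar),
                 tolerance = 1e-6)
})

test_that("confidence-bound acquisition behaves in kappa", {
    set.seed(13)
    X <- matrix(runif(10), 5, 2)
    y <- runif(5)
    model <- fitSurrogate(X, y, nRestarts = 4, seed = 1)
    xq <- matrix(c(0.3, 0.7), 1, 2)
    expect_equal(acquisitionValue(model, xq, kappa = 0),
                 predictSurrogate(model, xq)$mean)
    a1 <- acquisitionValue(model, xq, kappa = 1)
    a2 <- acquisitionValue(model, xq, kappa = 3)
    expect_true(a2 >= a1)
    # matches mean + kappa * sd from the independent oracle
    want <- gpOracle(model, xq)
    expect_equal(acquisitionValue(model, xq, kappa = 2),
                 want$mean + 2 * want$sd, tolerance = 1e-6)
    # the literal lower-bound direction
    expect_equal(acquisitionValue(model, xq, kappa = 2, direction = "min"),
                 want$mean - 2 * want$sd, tolerance = 1e-6)
    expect_error(acquisitionValue(model, xq, kappa = -1), "kappa")
})

test_that("single-point suggestion finds the acquisition maximizer", {
    # 2-D toy model; compare against a dense-grid search
    set.seed(14)
    X <- matrix(runif(14), 7, 2)
    y <- -(X[, 1] - 0.3)^2 - (X[, 2] - 0.6)^2
    model <- fitSurrogate(X, y, nRestarts = 6, seed = 5)
    sp <- ProcessSpace(c("a", "b"), 0, 1)
    pick <- suggestBatch(model, sp, batchSize = 1, kappa = 1, seed = 2,
                         nStarts = 12)
    g <- as.matrix(expand.grid(seq(0, 1, length.out = 101),
                               seq(0, 1, length.out = 101)))
    vals <- acquisitionValue(model, g, kappa = 1)
    best <- max(vals)
    expect_gte(acquisitionValue(model, matrix(pick, 1, 2), kappa = 1),
               best - 1e-4)
})

test_that("suggested batches are distinct, in bounds, and spread with kappa", {
    set.seed(15)
    X <- matrix(runif(20), 10, 2)
    y <- X[, 1] + rnorm(10, 0, 0.05)
    model <- fitSurrogate(X, y, nRestarts = 4, seed = 1)
    sp <- ProcessSpace(c("a", "b"), c(0, 2), c(1, 4))
    B <- suggestBatch(model, sp, batchSize = 6, kappa = 2, seed = 3,
                      nStarts = 4)
    expect_equal(nrow(B), 6L)
    expect_equal(anyDuplicated(B), 0L)
    expect_true(all(B[, 1] >= 0 & B[, 1] <= 1))
    expect_true(all(B[, 2] >= 2 & B[, 2] <= 4))
    # determinism
    expect_identical(B, suggestBatch(model, sp, batchSize = 6, kappa = 2,
                                     seed = 3, nStarts = 4))
    # with very large kappa the batch explores: it sits farther from the
    # training data than the pure-exploitation batch
    minDist <- function(batch) {
        U <- toUnitCube(sp, batch)
        min(apply(U, 1, function(u)
            min(sqrt(rowSums(sweep(X, 2, u)^2)))))
    }
    Bexplore <- suggestBatch(model, sp, batchSize = 6, kappa = 50, seed = 3,
                             nStarts = 6)
    Bexploit <- suggestBatch(model, sp, batchSize = 6, kappa = 0, seed = 3,
                             nStarts = 6)
    expect_gte(minDist(Bexplore), minDist(Bexploit))
})

test_that("process-space configs read from YAML and JSON", {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("dimensions:",
                 "  - {name: CoStock, lower: 0, upper: 2}",
                 "  - {name: AcOH, lower: 0, upper: 5, step: 0.5}"), f)
    sp <- readProcessSpace(f)
    expect_equal(dimNames(sp), c("CoStock", "AcOH"))
    expect_equal(unname(upperBounds(sp)), c(2, 5))
    j <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(dimensions = list(
        list(name = "a", lower = 0, upper = 1))), j, auto_unbox = TRUE)
    expect_equal(nDims(readProcessSpace(j)), 1L)
})
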