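test_that("top-peak divergence follows the set-overlap rule", {
    expect_equal(divergenceFromStartingMaterials(1:5, list(1:5)), 0)
    expect_equal(divergenceFromStartingMaterials(1:5, list(6:10, 11:15)), 1)
    # sharing 2 of 5 with A and 5 of 5 with B -> mean(0.6, 0) = 0.3
    expect_equal(
        divergenceFromStartingMaterials(
            c(100L, 101L, 102L, 103L, 104L),
            list(c(100L, 101L, 200L, 201L, 202L),
                 c(100L, 101L, 102L, 103L, 104L))),
        0.3)
    # unequal sizes use max cardinality in the denominator
    expect_equal(divergenceFromStartingMaterials(c(1L, 2L), list(1:4)),
                 1 - 2 / 4)
    # invariant under permutation of the starting-material list
    sms <- list(c(1L, 2L, 9L), c(4L, 5L), c(1L, 7L))
    expect_equal(divergenceFromStartingMaterials(1:5, sms),
                 divergenceFromStartingMaterials(1:5, rev(sms)))
    expect_error(divergenceFromStartingMaterials(1:5, list()), "starting")
})

test_that("non-starting-material peaks are the set difference", {
    expect_equal(nonSmPeaks(1:5, 1:5), integer())
    expect_equal(nonSmPeaks(1:5, 6:10), 1:5)
    set.seed(3)
    for (rep in 1:5) {
        a <- sample(1000, 200); b <- sample(1000, 200)
        expect_equal(nonSmPeaks(a, b), sort(a[!a %in% b]))
    }
})

test_that("frequency table tallies bin occurrence over the dataset", {
    single <- buildFrequencyTable(list(c(100L, 250L)))
    expect_equal(unname(peakCounts(single)), c(1L, 1L))
    allShared <- buildFrequencyTable(rep(list(c(100L, 250L)), 7))
    expect_equal(unname(peakCounts(allShared)), c(7L, 7L))
    expect_equal(datasetSize(allShared), 7L)

    # brute-force tally oracle on 50 random peak sets
    set.seed(21)
    sets <- lapply(1:50, function(i) sort(sample(200:400, sample(5:30, 1))))
    tab <- buildFrequencyTable(sets)
    for (b in as.integer(names(peakCounts(tab)))) {
        expect_equal(unname(peakCounts(tab)[as.character(b)]),
                     sum(vapply(sets, function(s) b %in% s, logical(1))))
    }
})

test_that("novel peaks are weighted by inverse dataset frequency", {
    tab <- new("PeakFrequencyTable",
               counts = c(`100` = 1L, `200` = 2L, `300` = 4L),
               datasetSize = 4L)
    expect_equal(weightedNoveltyCount(integer(), tab), 0)
    expect_equal(weightedNoveltyCount(100L, tab), 1)
    expect_equal(weightedNoveltyCount(c(100L, 200L, 300L), tab), 1.75)
    expect_error(weightedNoveltyCount(999L, tab), "stale")
})

test_that("feature scaling maps to [0,1] with degenerate input to zero", {
    expect_equal(featureScale(c(1, 2, 3)), c(0, 0.5, 1))
    expect_equal(featureScale(rep(4, 5)), rep(0, 5))
    set.seed(5)
    v <- rnorm(40)
    fs <- featureScale(v)
    expect_equal(fs[which.min(v)], 0)
    expect_equal(fs[which.max(v)], 1)
    expect_true(all(fs >= 0 & fs <= 1))
})

# a small deterministic dataset: 2 SMs, experiments across 3 temperatures
makeScoringFixture <- function() {
    sm1 <- makeSpec(c(300, 310, 320, 330, 340), c(100, 90, 80, 70, 60),
                    id = "sm1", role = "starting_material")
    sm2 <- makeSpec(c(500, 510, 520, 530, 540), c(100, 90, 80, 70, 60),
                    id = "sm2", role = "starting_material")
    exps <- list()
    temps <- c("ambient", "warm", "solvothermal")
    set.seed(17)
    for (ci in 1:4) {
        comp <- c(x = ci / 10, y = 1 - ci / 10)
        for (tp in temps) {
            if (ci == 1) {  # clone of sm1: should be least novel
                mzv <- mz(sm1); iv <- intensity(sm1)
            } else {
                novel <- 600 + ci * 20 + seq_len(ci + 1)
                mzv <- c(mz(sm1), novel)
                iv <- c(intensity(sm1), rep(95, length(novel)))
            }
            exps[[length(exps) + 1L]] <-
                makeSpec(mzv, iv, id = paste0("e", ci, "_", tp),
                         composition = comp, temperature = tp,
                         iteration = 1L)
        }
    }
    list(exps = exps, sms = list(sm1, sm2))
}

test_that("dataset scoring combines scaled halves and averages temperatures", {
    fx <- makeScoringFixture()
    sc <- scoreDataset(fx$exps, fx$sms)
    rec <- sc$records
    expect_true(all(rec$combined >= 0 & rec$combined <= 1))
    # both scaled halves attain 0 and 1 somewhere (halves non-constant here)
    expect_equal(range(rec$half1Scaled), c(0, 1))
    expect_equal(range(rec$half2Scaled), c(0, 1))
    expect_equal(rec$combined, (rec$half1Scaled + rec$half2Scaled) / 2)
    # the starting-material clone is the dataset minimum
    cloneRows <- grepl("^e1_", rec$spectrumId)
    expect_equal(rec$combined[cloneRows], rep(min(rec$combined), 3))
    # composition aggregate equals the mean over its temperatures
    for (k in unique(rec$compositionKey)) {
        expect_equal(sc$compositions$score[sc$compositions$compositionKey == k],
                     mean(rec$combined[rec$compositionKey == k]))
    }
    # bit-identical on rerun
    sc2 <- scoreDataset(fx$exps, fx$sms)
    expect_identical(sc, sc2)
    # metadata is mandatory
    bad <- makeSpec(c(100, 200), c(1, 2), id = "nometa")
    expect_error(scoreDataset(c(fx$exps, bad), fx$sms), "metadata|composition")
})

test_that("rescoring with appended data never changes half-1 raw values", {
    fx <- makeScoringFixture()
    before <- scoreDataset(fx$exps, fx$sms)$records
    extra <- makeSpec(c(700, 710, 720, 730, 740), rep(80, 5), id = "new1",
                      composition = c(x = 0.9, y = 0.1),
                      temperature = "ambient", iteration = 2L)
    # the new composition has one temperature; that incompleteness warning
    # is expected and not under test here
    after <- suppressWarnings(
        scoreDataset(c(fx$exps, list(extra)), fx$sms)$records)
    m <- match(before$spectrumId, after$spectrumId)
    expect_equal(before$half1Raw, after$half1Raw[m])
})

test_that("duplicating an experiment only shrinks other half-2 raw scores", {
    fx <- makeScoringFixture()
    before <- scoreDataset(fx$exps, fx$sms)$records
    dup <- fx$exps[[6]]
    dup@sourceId <- "dup"
    after <- scoreDataset(c(fx$exps, list(dup)), fx$sms)$records
    m <- match(before$spectrumId, after$spectrumId)
    expect_true(all(after$half2Raw[m] <= before$half2Raw + 1e-12))
})

test_that("missing temperature replicates average over those present with a warning", {
    fx <- makeScoringFixture()
    expect_warning(sc <- scoreDataset(fx$exps[-2], fx$sms), "replicates")
    rec <- sc$records
    k <- rec$compositionKey[rec$spectrumId == "e1_ambient"]
    expect_equal(sc$compositions$score[sc$compositions$compositionKey == k],
                 mean(rec$combined[rec$compositionKey == k]))
    expect_equal(sc$compositions$nTemperatures[
        sc$compositions$compositionKey == k], 2)
})
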