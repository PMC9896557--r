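#' @include AllClasses.R
NULL

#' Top-peak divergence from starting materials
#'
#' First half of the novelty score: how different an experiment's most
#' intense peaks are from each starting material's most intense peaks. For
#' each starting-material peak set s the divergence is
#' `1 - |exp ∩ s| / max(|exp|, |s|)`; the mean over starting materials is
#' returned. 0 means the top peaks coincide with a starting material
#' everywhere; 1 means they are fully disjoint from all of them.
#'
#' @param expTop integer bin vector: top peaks of the experiment.
#' @param smTops list of integer bin vectors, one per starting material.
#' @return a fraction in [0, 1].
#' @export
divergenceFromStartingMaterials <- function(expTop, smTops) {
    if (!length(expTop)) stop("experiment peak set is empty")
    if (!is.list(smTops) || !length(smTops))
        stop("at least one starting-material peak set required")
    d <- vapply(smTops, function(s) {
        1 - length(intersect(expTop, s)) / max(length(expTop), length(s))
    }, numeric(1))
    mean(d)
}

#' Peaks not attributable to starting materials
#'
#' Second-half input of the novelty score: the experiment bins (already
#' above the noise threshold) that appear in no starting-material
#' spectrum.
#'
#' @param exp integer bin vector of the experiment.
#' @param smUnion integer bin vector: union of all starting-material bins,
#'   binned identically.
#' @return sorted integer vector (possibly empty).
#' @export
nonSmPeaks <- function(exp, smUnion) {
    sort(setdiff(as.integer(exp), as.integer(smUnion)))
}

#' Tally peak occurrence across the accumulated dataset
#'
#' Counts, for every bin, the number of experiment peak sets containing
#' it, over the entire dataset accumulated so far (all iterations, all
#' temperatures). Novel-peak weights are the inverse of these counts, and
#' must be rebuilt whenever new experiments arrive so the weighting covers
#' the full dataset.
#'
#' @param peakSets non-empty list of integer bin vectors (one per
#'   experiment spectrum).
#' @return a [PeakFrequencyTable-class].
#' @export
buildFrequencyTable <- function(peakSets) {
    if (!is.list(peakSets) || !length(peakSets))
        stop("dataset must be a non-empty list of peak sets")
    bins <- unlist(lapply(peakSets, function(p) unique(as.integer(p))))
    counts <- table(bins)
    new("PeakFrequencyTable",
        counts = stats::setNames(as.integer(counts), names(counts)),
        datasetSize = length(peakSets))
}

#' Inverse-frequency-weighted count of novel peaks
#'
#' Second half of the novelty score: each non-starting-material peak
#' contributes 1/(number of experiment spectra containing it), so commonly
#' occurring peaks contribute less than rare ones. A peak seen only in
#' this experiment contributes exactly 1.
#'
#' @param unique integer bin vector of novel (non-starting-material) peaks.
#' @param table a [PeakFrequencyTable-class] covering the full dataset.
#' @return non-negative weighted count.
#' @export
weightedNoveltyCount <- function(unique, table) {
    stopifnot(is(table, "PeakFrequencyTable"))
    if (!length(unique)) return(0)
    key <- as.character(as.integer(unique))
    missing <- key[!key %in% names(peakCounts(table))]
    if (length(missing))
        stop("frequency table is stale: bins absent: ",
             paste(missing, collapse = ", "))
    sum(1 / peakCounts(table)[key])
}

#' Min-max feature scaling to [0, 1]
#'
#' `(v - min) / (max - min)`. A constant vector carries no discriminating
#' signal and maps to all zeros.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector in [0, 1].
#' @export
featureScale <- function(values) {
    if (!length(values)) stop("cannot scale an empty vector")
    rng <- range(values)
    if (rng[1] == rng[2]) return(rep(0, length(values)))
    (values - rng[1]) / (rng[2] - rng[1])
}

#' Score a dataset of experiment spectra for novelty
#'
#' Computes the two-part serendipity score for every experiment spectrum
#' against the starting-material references, then aggregates to one score
#' per composition:
#' \enumerate{
#'   \item threshold all spectra at `relThreshold` of their base peak;
#'   \item half (i): divergence of the `topN` most intense binned peaks
#'     from each starting material's `topN` peaks, averaged over starting
#'     materials;
#'   \item half (ii): inverse-frequency-weighted count of binned peaks not
#'     present in any starting material, with frequencies tallied over the
#'     full accumulated dataset;
#'   \item each half is min-max feature-scaled across all experiment
#'     spectra (so the halves weigh evenly) and the two are averaged;
#'   \item per composition, combined scores are averaged over the
#'     temperatures present (missing replicates are averaged over, with a
#'     warning).
#' }
#' Rescoring after appending experiments changes earlier records only
#' through the scaling and the frequency weights, never through half (i)
#' raw values. The computation is deterministic.
#'
#' @param experiments list of [Spectrum-class] with `role = "experiment"`,
#'   each carrying composition and temperature metadata.
#' @param startingMaterials non-empty list of starting-material
#'   [Spectrum-class].
#' @param relThreshold noise threshold (fraction of base peak), default 1%.
#' @param topN top-peak window for half (i), default 5.
#' @return list with elements
#'   \describe{
#'     \item{records}{data.frame, one row per experiment spectrum:
#'       `spectrumId, compositionKey, temperature, iteration, half1Raw,
#'       half2Raw, half1Scaled, half2Scaled, combined`.}
#'     \item{compositions}{data.frame, one row per composition:
#'       `compositionKey`, the composition columns, `nTemperatures`,
#'       `score` (the temperature-averaged combined score in [0, 1]).}
#'     \item{frequencyTable}{the [PeakFrequencyTable-class] used.}
#'   }
#' @export
scoreDataset <- function(experiments, startingMaterials,
                         relThreshold = 0.01, topN = 5L) {
    if (!length(experiments)) stop("no experiment spectra supplied")
    if (!length(startingMaterials)) stop("no starting-material spectra supplied")
    for (s in experiments) {
        if (!is(s, "Spectrum")) stop("experiments must be Spectrum objects")
        if (!length(composition(s)) || is.na(temperature(s)))
            stop("experiment '", sourceId(s),
                 "' lacks composition or temperature metadata")
    }
    smThr <- lapply(startingMaterials, applyNoiseThreshold, relThreshold)
    smTops <- lapply(smThr, topNPeaks, topN)
    smUnion <- sort(unique(unlist(lapply(smThr, binPeaks))))

    expThr <- lapply(experiments, applyNoiseThreshold, relThreshold)
    expBins <- lapply(expThr, binPeaks)
    freq <- buildFrequencyTable(expBins)

    half1 <- vapply(expThr, function(s)
        divergenceFromStartingMaterials(topNPeaks(s, topN), smTops), numeric(1))
    half2 <- vapply(seq_along(expThr), function(i)
        weightedNoveltyCount(nonSmPeaks(expBins[[i]], smUnion), freq),
        numeric(1))

    h1s <- featureScale(half1)
    h2s <- featureScale(half2)
    combined <- (h1s + h2s) / 2

    records <- data.frame(
        spectrumId = vapply(experiments, sourceId, ""),
        compositionKey = vapply(experiments,
                                function(s) .compositionKey(composition(s)), ""),
        temperature = vapply(experiments, temperature, ""),
        iteration = vapply(experiments, iteration, NA_integer_),
        half1Raw = half1, half2Raw = half2,
        half1Scaled = h1s, half2Scaled = h2s,
        combined = combined,
        stringsAsFactors = FALSE)

    keys <- unique(records$compositionKey)
    nTempsSeen <- length(unique(records$temperature))
    compRows <- lapply(keys, function(k) {
        sub <- records[records$compositionKey == k, ]
        if (nrow(sub) < nTempsSeen)
            warning("composition ", k, ": only ", nrow(sub), " of ",
                    nTempsSeen, " temperature replicates present; ",
                    "averaging over those available")
        comp <- composition(experiments[[match(k, records$compositionKey)]])
        out <- as.data.frame(as.list(comp))
        if (!length(comp)) out <- data.frame(row.names = 1L)
        cbind(data.frame(compositionKey = k, stringsAsFactors = FALSE), out,
              data.frame(nTemperatures = length(unique(sub$temperature)),
                         score = mean(sub$combined)))
    })
    compositions <- do.call(rbind, compRows)
    rownames(compositions) <- NULL

    list(records = records, compositions = compositions,
         frequencyTable = freq)
}

#' Export a frequency table as JSON
#'
#' @param table a [PeakFrequencyTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(table, path) {
    stopifnot(is(table, "PeakFrequencyTable"))
    jsonlite::write_json(
        list(datasetSize = datasetSize(table),
             counts = as.list(peakCounts(table))),
        path, auto_unbox = TRUE)
    invisible(path)
}
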