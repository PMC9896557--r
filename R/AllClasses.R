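#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Spectrum
## ---------------------------------------------------------------------------

#' Spectrum: a canonicalized mass-spectral peak list with metadata
#'
#' One experiment's (or one starting material's) centroided peak list.
#' Construction canonicalizes: peaks are sorted by m/z and exact duplicate
#' m/z rows are merged by summing intensities (centroided exports sometimes
#' split a peak over two rows).
#'
#' @slot peaks data.frame with numeric columns `mz` (Thomson, > 0) and
#'   `intensity` (arbitrary units, >= 0), strictly increasing in `mz`.
#' @slot sourceId opaque experiment identifier.
#' @slot role `"experiment"` or `"starting_material"`.
#' @slot composition named numeric vector locating the experiment in the
#'   process space (may be empty for starting materials).
#' @slot temperature temperature label (e.g. `"ambient"`); may be `NA`.
#' @slot iteration non-negative integer campaign iteration; may be `NA`.
#'
#' @export
setClass("Spectrum",
    representation(
        peaks = "data.frame",
        sourceId = "character",
        role = "character",
        composition = "numeric",
        temperature = "character",
        iteration = "integer"
    ),
    prototype(
        peaks = data.frame(mz = numeric(), intensity = numeric()),
        sourceId = NA_character_,
        role = "experiment",
        composition = numeric(),
        temperature = NA_character_,
        iteration = NA_integer_
    )
)

setValidity("Spectrum", function(object) {
    p <- object@peaks
    msg <- character()
    if (!all(c("mz", "intensity") %in% names(p)))
        msg <- c(msg, "peaks must have columns 'mz' and 'intensity'")
    else {
        if (nrow(p) && any(p$mz <= 0)) msg <- c(msg, "all m/z must be > 0")
        if (nrow(p) && any(p$intensity < 0))
            msg <- c(msg, "intensities must be >= 0")
        if (nrow(p) > 1L && any(diff(p$mz) <= 0))
            msg <- c(msg, "m/z must be strictly increasing (canonical form)")
    }
    if (!object@role %in% c("experiment", "starting_material"))
        msg <- c(msg, "role must be 'experiment' or 'starting_material'")
    if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param mz,intensity numeric vectors of equal length; rows are sorted by
#'   m/z and exact duplicate m/z merged by intensity sum.
#' @param sourceId experiment identifier.
#' @param role `"experiment"` (default) or `"starting_material"`.
#' @param composition optional named numeric process-space point.
#' @param temperature optional temperature label.
#' @param iteration optional non-negative integer.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(c(200, 100, 150), c(20, 10, 5), sourceId = "exp1")
#' mz(s)
#' @export
Spectrum <- function(mz, intensity, sourceId = NA_character_,
                     role = c("experiment", "starting_material"),
                     composition = numeric(), temperature = NA_character_,
                     iteration = NA_integer_) {
    role <- match.arg(role)
    if (length(mz) != length(intensity))
        stop("mz and intensity must have equal length")
    if (length(mz) == 0L)
        stop("empty spectrum: no peaks")
    o <- order(mz)
    mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
    if (anyDuplicated(mz)) {
        intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
        mz <- unique(mz)
    }
    new("Spectrum",
        peaks = data.frame(mz = mz, intensity = intensity),
        sourceId = as.character(sourceId), role = role,
        composition = composition,
        temperature = as.character(temperature),
        iteration = as.integer(iteration))
}

#' @rdname accessors
#' @export
setMethod("peakTable", "Spectrum", function(object) object@peaks)
#' @rdname accessors
#' @export
setMethod("mz", "Spectrum", function(object) object@peaks$mz)
#' @rdname accessors
#' @export
setMethod("intensity", "Spectrum", function(object) object@peaks$intensity)
#' @rdname accessors
#' @export
setMethod("sourceId", "Spectrum", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("spectrumRole", "Spectrum", function(object) object@role)
#' @rdname accessors
#' @export
setMethod("composition", "Spectrum", function(object) object@composition)
#' @rdname accessors
#' @export
setMethod("temperature", "Spectrum", function(object) object@temperature)
#' @rdname accessors
#' @export
setMethod("iteration", "Spectrum", function(object) object@iteration)
#' @rdname accessors
#' @export
setMethod("nPeaks", "Spectrum", function(object) nrow(object@peaks))

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum '", object@sourceId, "' (", object@role, ")\n", sep = "")
    cat("  ", nrow(object@peaks), " peaks, m/z ",
        if (nrow(object@peaks)) paste0(round(min(object@peaks$mz), 2), "-",
                                       round(max(object@peaks$mz), 2)) else "-",
        "\n", sep = "")
    if (length(object@composition))
        cat("  composition: ",
            paste0(names(object@composition), "=",
                   signif(object@composition, 4), collapse = ", "), "\n",
            sep = "")
    if (!is.na(object@temperature))
        cat("  temperature: ", object@temperature,
            if (!is.na(object@iteration))
                paste0("  iteration: ", object@iteration), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PeakFrequencyTable
## ---------------------------------------------------------------------------

#' PeakFrequencyTable: dataset-wide peak occurrence counts
#'
#' For every binned m/z observed in the accumulated set of experiment
#' spectra, the number of experiment spectra containing that bin. Used to
#' weight novel peaks by inverse frequency, so commonly occurring peaks
#' contribute less than rare ones.
#'
#' @slot counts named integer vector: bin (as character m/z) -> count.
#' @slot datasetSize number of experiment spectra tallied.
#' @export
setClass("PeakFrequencyTable",
    representation(counts = "integer", datasetSize = "integer"))

setValidity("PeakFrequencyTable", function(object) {
    msg <- character()
    if (length(object@counts)) {
        if (is.null(names(object@counts)))
            msg <- c(msg, "counts must be named by bin")
        if (any(object@counts < 1L) || any(object@counts > object@datasetSize))
            msg <- c(msg, "counts must lie in [1, datasetSize]")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("peakCounts", "PeakFrequencyTable", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("datasetSize", "PeakFrequencyTable", function(object) object@datasetSize)

setMethod("show", "PeakFrequencyTable", function(object) {
    cat("PeakFrequencyTable: ", length(object@counts), " bins over ",
        object@datasetSize, " experiment spectra\n", sep = "")
})

## ---------------------------------------------------------------------------
## ProcessSpace
## ---------------------------------------------------------------------------

#' ProcessSpace: the box of reaction-composition variables
#'
#' An ordered list of named continuous composition dimensions (reagent
#' amounts) with lower/upper bounds and an optional discretization step.
#' Internally all sampling and surrogate modelling happens on the unit
#' hypercube; [toUnitCube()]/[fromUnitCube()] convert.
#'
#' @slot dimensions data.frame with columns `name`, `lower`, `upper`, `step`
#'   (`NA` step = continuous).
#' @export
setClass("ProcessSpace", representation(dimensions = "data.frame"))

setValidity("ProcessSpace", function(object) {
    d <- object@dimensions
    msg <- character()
    if (!all(c("name", "lower", "upper", "step") %in% names(d)))
        msg <- c(msg, "dimensions needs columns name, lower, upper, step")
    else {
        if (nrow(d) < 1L) msg <- c(msg, "at least one dimension required")
        if (any(d$lower >= d$upper)) msg <- c(msg, "lower must be < upper")
        if (anyDuplicated(d$name)) msg <- c(msg, "dimension names must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProcessSpace
#'
#' @param names character vector of dimension (reagent) names.
#' @param lower,upper numeric bounds per dimension (recycled if scalar).
#' @param step optional discretization step per dimension (`NA` = continuous),
#'   e.g. the resolution of a liquid-handler dispense.
#' @return a [ProcessSpace-class].
#' @examples
#' sp <- ProcessSpace(c("CoStock", "AcOH", "pyridine"), 0, c(2, 5, 5))
#' nDims(sp)
#' @export
ProcessSpace <- function(names, lower = 0, upper = 1, step = NA_real_) {
    k <- length(names)
    new("ProcessSpace", dimensions = data.frame(
        name = as.character(names),
        lower = rep_len(as.numeric(lower), k),
        upper = rep_len(as.numeric(upper), k),
        step = rep_len(as.numeric(step), k)))
}

#' @rdname accessors
#' @export
setMethod("dimNames", "ProcessSpace", function(object) object@dimensions$name)
#' @rdname accessors
#' @export
setMethod("nDims", "ProcessSpace", function(object) nrow(object@dimensions))
#' @rdname accessors
#' @export
setMethod("lowerBounds", "ProcessSpace", function(object) {
    stats::setNames(object@dimensions$lower, object@dimensions$name)
})
#' @rdname accessors
#' @export
setMethod("upperBounds", "ProcessSpace", function(object) {
    stats::setNames(object@dimensions$upper, object@dimensions$name)
})

setMethod("show", "ProcessSpace", function(object) {
    d <- object@dimensions
    cat("ProcessSpace with", nrow(d), "dimensions:\n")
    for (i in seq_len(nrow(d)))
        cat(sprintf("  %-12s [%g, %g]%s\n", d$name[i], d$lower[i], d$upper[i],
                    if (is.na(d$step[i])) "" else sprintf(" step %g", d$step[i])))
})

## ---------------------------------------------------------------------------
## GPSurrogate
## ---------------------------------------------------------------------------

#' GPSurrogate: Gaussian-process surrogate of the novelty landscape
#'
#' A zero-mean (after centring) Gaussian process over the unit hypercube
#' with an anisotropic Matern-5/2 kernel plus a white-noise term, fitted by
#' maximizing the log marginal likelihood. Produced by [fitSurrogate()];
#' query with [predictSurrogate()].
#'
#' @slot X training inputs, rows in the unit hypercube.
#' @slot y training targets (aggregate novelty scores).
#' @slot params list: `lengthScales` (per dimension), `signalVar`,
#'   `noiseVar`, all > 0.
#' @slot meanY constant prior mean subtracted from `y` before fitting.
#' @slot L upper Cholesky factor of the training covariance (internal).
#' @slot alpha precomputed K^-1 (y - meanY) (internal).
#' @slot logLik maximized log marginal likelihood.
#' @export
setClass("GPSurrogate",
    representation(X = "matrix", y = "numeric", params = "list",
                   meanY = "numeric", L = "matrix", alpha = "numeric",
                   logLik = "numeric"))

setValidity("GPSurrogate", function(object) {
    msg <- character()
    if (nrow(object@X) != length(object@y))
        msg <- c(msg, "X and y sizes differ")
    p <- object@params
    if (any(unlist(p[c("lengthScales", "signalVar", "noiseVar")]) <= 0))
        msg <- c(msg, "kernel hyperparameters must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("hyperParameters", "GPSurrogate", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("trainingData", "GPSurrogate",
          function(object) list(X = object@X, y = object@y))

setMethod("show", "GPSurrogate", function(object) {
    p <- object@params
    cat("GPSurrogate on", length(object@y), "observations,",
        ncol(object@X), "dimensions\n")
    cat("  Matern-5/2 length scales:",
        paste(signif(p$lengthScales, 3), collapse = ", "), "\n")
    cat("  signal variance:", signif(p$signalVar, 4),
        " noise variance:", signif(p$noiseVar, 4), "\n")
    cat("  log marginal likelihood:", signif(object@logLik, 6), "\n")
})

## ---------------------------------------------------------------------------
## BarcodeMatrix
## ---------------------------------------------------------------------------

#' BarcodeMatrix: binary experiment x peak presence matrix
#'
#' Rows are experiments, columns are the sorted union of binned m/z values
#' observed across the in-scope experiments; entry (i, j) is 1 iff
#' experiment i shows a peak in bin j. Input to the NMF deconvolution.
#'
#' @slot matrix integer 0/1 matrix; rownames = experiment ids, colnames =
#'   bin m/z (character).
#' @slot scope list describing the restriction used to build the matrix,
#'   e.g. `list(temperature = "solvothermal", iteration = NULL)`.
#' @export
setClass("BarcodeMatrix",
    representation(matrix = "matrix", scope = "list"))

setValidity("BarcodeMatrix", function(object) {
    m <- object@matrix
    msg <- character()
    if (!all(m %in% c(0L, 1L))) msg <- c(msg, "entries must be binary")
    if (ncol(m) && any(colSums(m) < 1L))
        msg <- c(msg, "every column must contain at least one 1")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "row (experiment) and column (bin) names required")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("barcodes", "BarcodeMatrix", function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("barcodeScope", "BarcodeMatrix", function(object) object@scope)

setMethod("show", "BarcodeMatrix", function(object) {
    cat("BarcodeMatrix: ", nrow(object@matrix), " experiments x ",
        ncol(object@matrix), " unique peak bins (",
        sum(object@matrix), " ones)\n", sep = "")
    sc <- object@scope
    if (length(sc))
        cat("  scope: ", paste0(names(sc), "=",
            vapply(sc, function(x) paste(x, collapse = ","), ""),
            collapse = "; "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ArchetypeModel
## ---------------------------------------------------------------------------

#' ArchetypeModel: NMF factor pair interpreting spectra as archetypes
#'
#' The non-negative factorization B ~ W H of a [BarcodeMatrix-class]. The
#' feature matrix W (m x k) gives each experiment's loading on every
#' archetype ("the composition of the MS spectrum for each experiment");
#' the coefficient matrix H (k x n) gives each archetype's loading on every
#' m/z bin - a fingerprint of co-occurring peaks interpreted as one product
#' distribution. Rows of H are scaled to unit maximum (with W compensated)
#' for comparability.
#'
#' @slot featureMatrix m x k non-negative matrix (rownames = experiments).
#' @slot coefficientMatrix k x n non-negative matrix (colnames = bins),
#'   rows scaled to unit maximum.
#' @slot rank chosen rank k (>= 2).
#' @slot rankErrors named numeric: Frobenius reconstruction error per
#'   screened rank (at least the fitted rank).
#' @slot seed integer seed used for factorization restarts.
#' @export
setClass("ArchetypeModel",
    representation(featureMatrix = "matrix", coefficientMatrix = "matrix",
                   rank = "integer", rankErrors = "numeric",
                   seed = "integer"))

setValidity("ArchetypeModel", function(object) {
    msg <- character()
    if (any(object@featureMatrix < 0) || any(object@coefficientMatrix < 0))
        msg <- c(msg, "factors must be elementwise non-negative")
    if (object@rank < 2L) msg <- c(msg, "rank must be >= 2")
    if (ncol(object@featureMatrix) != object@rank ||
        nrow(object@coefficientMatrix) != object@rank)
        msg <- c(msg, "factor shapes inconsistent with rank")
    if (!length(object@rankErrors))
        msg <- c(msg, "reconstruction error must be recorded")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("featureMatrix", "ArchetypeModel", function(object) object@featureMatrix)
#' @rdname accessors
#' @export
setMethod("coefficientMatrix", "ArchetypeModel",
          function(object) object@coefficientMatrix)
#' @rdname accessors
#' @export
setMethod("modelRank", "ArchetypeModel", function(object) object@rank)
#' @rdname accessors
#' @export
setMethod("rankErrors", "ArchetypeModel", function(object) object@rankErrors)

setMethod("show", "ArchetypeModel", function(object) {
    cat("ArchetypeModel: rank ", object@rank, " (",
        nrow(object@featureMatrix), " experiments x ",
        ncol(object@coefficientMatrix), " bins)\n", sep = "")
    cat("  reconstruction error at fitted rank:",
        signif(object@rankErrors[as.character(object@rank)], 5), "\n")
})

## ---------------------------------------------------------------------------
## GroundTruthSpace
## ---------------------------------------------------------------------------

#' GroundTruthSpace: a synthetic process space with planted archetypes
#'
#' A simulated ground truth for benchmarking the pipeline: latent product
#' distributions ("archetypes") are planted as disjoint m/z fingerprints
#' expressed in smooth radial bumps of the composition space; everywhere
#' else only starting-material peaks appear. [simulateSpectrum()] draws
#' noisy spectra from it.
#'
#' @slot space the [ProcessSpace-class] being emulated.
#' @slot archetypes list; each element has `fingerprint` (integer bins),
#'   `center` (unit-cube coordinates), `radius`, `maxExpression`, and
#'   `tempFactor` (named per-temperature expression multipliers).
#' @slot smSpectra list of starting-material [Spectrum-class] objects.
#' @slot noise list: `dropout` (per-peak omission probability),
#'   `spuriousRate` (Poisson mean of noise peaks), `sdlog` (log-normal
#'   intensity spread).
#' @slot temperatures character vector of temperature labels.
#' @slot mzRange integer range for peak placement.
#' @slot seed generation seed.
#' @export
setClass("GroundTruthSpace",
    representation(space = "ProcessSpace", archetypes = "list",
                   smSpectra = "list", noise = "list",
                   temperatures = "character", mzRange = "integer",
                   seed = "integer"))

setValidity("GroundTruthSpace", function(object) {
    msg <- character()
    fps <- lapply(object@archetypes, `[[`, "fingerprint")
    if (length(fps) > 1L) {
        keys <- vapply(fps, function(f) paste(sort(f), collapse = ","), "")
        if (anyDuplicated(keys)) msg <- c(msg, "fingerprints must be distinct")
    }
    for (a in object@archetypes)
        if (a$maxExpression < 0 || a$maxExpression > 1)
            msg <- c(msg, "expression levels must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthSpace", function(object) {
    cat("GroundTruthSpace:", length(object@archetypes),
        "planted archetypes in", nDims(object@space), "dimensions;",
        length(object@smSpectra), "starting materials\n")
})

## ---------------------------------------------------------------------------
## CampaignState
## ---------------------------------------------------------------------------

#' CampaignState: persistent state of an exploration campaign
#'
#' Ties the score -> suggest -> (simulate/measure) loop together: the
#' accumulated experiment manifest, per-iteration score tables, the peak
#' frequency snapshot and all seeds, persisted as JSON in the campaign
#' directory. All randomness flows from one master seed via named
#' substreams so a reloaded campaign rescores bit-identically.
#'
#' @slot version state-format version string (checked on load).
#' @slot dir campaign directory holding state and artifacts.
#' @slot space the [ProcessSpace-class] being explored.
#' @slot config list of metric/GP/NMF settings.
#' @slot seed master seed.
#' @slot iteration number of completed score/suggest cycles.
#' @slot manifest accumulated experiment manifest (data.frame).
#' @slot scores latest composition-score table (data.frame).
#' @export
setClass("CampaignState",
    representation(version = "character", dir = "character",
                   space = "ProcessSpace", config = "list",
                   seed = "integer", iteration = "integer",
                   manifest = "data.frame", scores = "data.frame"))

setMethod("show", "CampaignState", function(object) {
    cat("CampaignState (v", object@version, ") in ", object@dir, "\n",
        sep = "")
    cat("  iteration ", object@iteration, "; ", nrow(object@manifest),
        " manifest rows\n", sep = "")
})
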