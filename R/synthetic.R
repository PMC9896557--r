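#' @include AllClasses.R
NULL

#' Generate a synthetic ground-truth process space
#'
#' Builds a simulated exploration problem: latent product distributions
#' ("archetypes") are planted as disjoint integer m/z fingerprints, each
#' expressed inside a smooth radial bump of the composition space
#' (`expression(x) = maxExpression * tempFactor * exp(-|x - c|^2 / 2 r^2)`
#' on unit-cube coordinates). Away from all bumps only starting-material
#' peaks appear. Fully reproducible for a fixed seed.
#'
#' @param config list overriding any of: `nDims` (6), `nArchetypes` (4),
#'   `fingerprintSize` (range, c(6, 12)), `radius` (0.25), `centerRange`
#'   (unit-cube interval for bump centers, c(0, 1)), `nSm` (2), `smPeaks`
#'   (8), `mzRange` (c(150, 900)), `temperatures` (ambient/warm/
#'   solvothermal), `dropout` (0.05), `spuriousRate` (2), `sdlog` (0.5),
#'   `dimNames`.
#' @param seed integer seed.
#' @return a [GroundTruthSpace-class].
#' @export
generateSpace <- function(config = list(), seed = 1L) {
    cfg <- utils::modifyList(list(
        nDims = 6L, nArchetypes = 4L, fingerprintSize = c(6L, 12L),
        radius = 0.25, centerRange = c(0, 1), nSm = 2L, smPeaks = 8L,
        mzRange = c(150L, 900L),
        temperatures = c("ambient", "warm", "solvothermal"),
        dropout = 0.05, spuriousRate = 2, sdlog = 0.5,
        dimNames = NULL), config)
    set.seed(seed)
    d <- cfg$nDims
    nm <- cfg$dimNames
    if (is.null(nm)) nm <- paste0("reagent", seq_len(d))
    space <- ProcessSpace(nm, 0, 1)

    bins <- seq(cfg$mzRange[1L], cfg$mzRange[2L])
    smBins <- sort(sample(bins, cfg$nSm * cfg$smPeaks))
    avail <- setdiff(bins, smBins)
    maxFp <- cfg$fingerprintSize[length(cfg$fingerprintSize)]
    if (cfg$nArchetypes * maxFp > length(avail))
        stop("infeasible config: more fingerprint peaks than available bins")

    smSpectra <- list()
    smSplit <- split(smBins, rep(seq_len(cfg$nSm), each = cfg$smPeaks))
    for (i in seq_len(cfg$nSm)) {
        mzv <- sort(smSplit[[i]])
        smSpectra[[i]] <- Spectrum(
            mzv, stats::rlnorm(length(mzv), log(300), 0.3),
            sourceId = paste0("SM", i), role = "starting_material")
    }

    archetypes <- list()
    pool <- avail
    for (a in seq_len(cfg$nArchetypes)) {
        sz <- if (length(cfg$fingerprintSize) > 1L)
            sample(seq(cfg$fingerprintSize[1L], cfg$fingerprintSize[2L]), 1L)
        else cfg$fingerprintSize
        fp <- sort(sample(pool, sz))
        pool <- setdiff(pool, fp)
        archetypes[[a]] <- list(
            fingerprint = as.integer(fp),
            center = stats::runif(d, cfg$centerRange[1L], cfg$centerRange[2L]),
            radius = cfg$radius,
            maxExpression = stats::runif(1, 0.85, 1),
            tempFactor = stats::setNames(stats::runif(length(cfg$temperatures),
                                                      0.7, 1),
                                         cfg$temperatures))
    }

    new("GroundTruthSpace", space = space, archetypes = archetypes,
        smSpectra = smSpectra,
        noise = list(dropout = cfg$dropout, spuriousRate = cfg$spuriousRate,
                     sdlog = cfg$sdlog),
        temperatures = cfg$temperatures,
        mzRange = as.integer(cfg$mzRange), seed = as.integer(seed))
}

#' Corner-concentrated benchmark ground truth
#'
#' A 2-dimensional ground truth whose archetype bumps all sit in one small
#' corner of the composition space, so a directed explorer has a concrete
#' advantage over uniform random sampling. Used by the closed-loop
#' benchmark.
#'
#' @param seed integer seed.
#' @param nArchetypes number of planted archetypes (default 4).
#' @return a [GroundTruthSpace-class].
#' @export
cornerGroundTruth <- function(seed = 1L, nArchetypes = 4L) {
    generateSpace(list(
        nDims = 2L, nArchetypes = nArchetypes,
        fingerprintSize = c(5L, 8L), radius = 0.12,
        centerRange = c(0.05, 0.30), spuriousRate = 1, dropout = 0.05),
        seed = seed)
}

## expression level of one archetype at a unit-cube point / temperature;
## responses below 1% are truncated to zero (an expression threshold: far
## from its bump a product is genuinely absent, not just rare)
.expressionLevel <- function(arch, u, temp) {
    tf <- if (temp %in% names(arch$tempFactor)) arch$tempFactor[[temp]] else 1
    resp <- arch$maxExpression * tf *
        exp(-sum((u - arch$center)^2) / (2 * arch$radius^2))
    if (resp < 0.01) 0 else resp
}

#' Simulate one experiment spectrum from a ground truth
#'
#' Draws a noisy ESI-MS-like peak list at a composition/temperature:
#' starting-material peaks (always present, log-normal intensity jitter),
#' each archetype's full fingerprint included with probability equal to
#' its local expression level, then thinned by per-peak dropout, with
#' log-normal intensities whose scale grows with expression; plus a
#' Poisson number of spurious low-intensity peaks at random m/z.
#'
#' @param gt a [GroundTruthSpace-class].
#' @param composition numeric point inside the space bounds (real units).
#' @param temp temperature label.
#' @param seed integer seed; fixed seed gives an identical spectrum.
#' @param sourceId identifier for the resulting [Spectrum-class].
#' @param iteration optional iteration tag.
#' @return a [Spectrum-class] with `role = "experiment"`.
#' @export
simulateSpectrum <- function(gt, composition, temp, seed = 1L,
                             sourceId = "sim", iteration = NA_integer_) {
    stopifnot(is(gt, "GroundTruthSpace"))
    lo <- lowerBounds(gt@space); up <- upperBounds(gt@space)
    if (any(composition < lo - 1e-12) || any(composition > up + 1e-12))
        stop("composition outside process-space bounds")
    u <- as.numeric(toUnitCube(gt@space, composition))
    set.seed(seed)
    noise <- gt@noise

    mzv <- numeric(); inten <- numeric()
    for (sm in gt@smSpectra) {
        mzv <- c(mzv, mz(sm) + stats::runif(nPeaks(sm), -0.2, 0.2))
        inten <- c(inten, intensity(sm) *
                       stats::rlnorm(nPeaks(sm), 0, noise$sdlog))
    }
    for (arch in gt@archetypes) {
        resp <- .expressionLevel(arch, u, temp)
        if (stats::runif(1) < resp) {
            keep <- stats::runif(length(arch$fingerprint)) >= noise$dropout
            fp <- arch$fingerprint[keep]
            if (length(fp)) {
                mzv <- c(mzv, fp + stats::runif(length(fp), -0.2, 0.2))
                inten <- c(inten, stats::rlnorm(length(fp),
                                                log(400 * resp + 50),
                                                noise$sdlog))
            }
        }
    }
    nSpur <- stats::rpois(1, noise$spuriousRate)
    if (nSpur > 0) {
        mzv <- c(mzv, stats::runif(nSpur, gt@mzRange[1L], gt@mzRange[2L]))
        inten <- c(inten, stats::rlnorm(nSpur, log(30), noise$sdlog))
    }
    cmp <- stats::setNames(as.numeric(composition), dimNames(gt@space))
    Spectrum(mzv, inten, sourceId = sourceId, role = "experiment",
             composition = cmp, temperature = temp, iteration = iteration)
}

## simulate a whole design at every temperature; returns list of Spectrum
.simulateBatch <- function(gt, X, iteration, seed, idPrefix = "exp") {
    out <- list()
    for (i in seq_len(nrow(X))) {
        for (temp in gt@temperatures) {
            sid <- paste0(idPrefix, "_i", iteration, "_c", i, "_", temp)
            out[[sid]] <- simulateSpectrum(
                gt, X[i, ], temp,
                seed = substreamSeed(seed, paste0("sim-", temp),
                                     iteration * 1000L + i),
                sourceId = sid, iteration = iteration)
        }
    }
    out
}

## count planted archetypes recovered from a set of experiment spectra:
## unique (non-SM) bins -> barcode -> rank screen -> NMF -> cosine match
.countDiscoveries <- function(gt, experiments, relThreshold = 0.01,
                              maxRank = 12L, seed = 1L, simThreshold = 0.8) {
    smThr <- lapply(gt@smSpectra, applyNoiseThreshold, relThreshold)
    smUnion <- sort(unique(unlist(lapply(smThr, binPeaks))))
    uniq <- lapply(experiments, function(s)
        nonSmPeaks(binPeaks(applyNoiseThreshold(s, relThreshold)), smUnion))
    if (!length(unlist(uniq))) return(0L)
    B <- buildBarcodeMatrix(uniq, scope = list(temperature = "all"))
    errs <- screenRanks(B, seed = seed, maxRank = maxRank)
    k <- selectRank(errs)
    if (k < 2L) k <- 2L
    model <- factorize(B, k, seed = seed, nRestarts = 3L, rankErrors = errs)
    planted <- .plantedFingerprintMatrix(gt)
    if (!nrow(planted)) return(0L)
    m <- matchArchetypes(planted, model, simThreshold = simThreshold)
    sum(m$pairing$shared)
}

## planted fingerprints as a binary matrix with bin colnames
.plantedFingerprintMatrix <- function(gt) {
    fps <- lapply(gt@archetypes, `[[`, "fingerprint")
    if (!length(fps))
        return(matrix(0, 0, 0))
    bins <- sort(unique(unlist(fps)))
    M <- matrix(0, length(fps), length(bins),
                dimnames = list(paste0("planted", seq_along(fps)),
                                as.character(bins)))
    for (i in seq_along(fps)) M[i, as.character(fps[[i]])] <- 1
    M
}

#' Closed-loop benchmark: directed vs random exploration
#'
#' Runs the full score-suggest-simulate loop against a ground truth for
#' each strategy and replicate seed: iteration 1 is a Latin hypercube
#' design for every strategy; later iterations come from GP Bayesian
#' optimization of the novelty score (`"gpbo"`) or uniform random
#' sampling (`"random"`). After the final iteration the accumulated
#' spectra are deconvoluted (barcodes, rank screen, NMF) and the
#' recovered fingerprints are matched against the planted ones at cosine
#' >= `simThreshold`; the count of planted archetypes discovered is
#' reported per replicate and strategy.
#'
#' @param gt a [GroundTruthSpace-class].
#' @param iterations number of batches per run (default 3).
#' @param batchSize compositions per batch (default 24).
#' @param strategies subset of `c("gpbo", "random")`.
#' @param seeds integer vector of replicate seeds (>= 5 recommended).
#' @param kappa acquisition exploration weight (default 2).
#' @param relThreshold noise threshold for scoring (default 1%).
#' @param maxRank rank-screen ceiling for the deconvolution (default 12).
#' @param gpRestarts,acqStarts surrogate-fit restarts and acquisition
#'   local-search starts (smaller = faster).
#' @param simThreshold cosine threshold for a discovery (default 0.8).
#' @return list: `perReplicate` data.frame (`seed`, `strategy`,
#'   `discovered`), `means` named numeric (mean discoveries per strategy).
#' @export
closedLoopBenchmark <- function(gt, iterations = 3L, batchSize = 24L,
                                strategies = c("gpbo", "random"),
                                seeds = 1:5, kappa = 2, relThreshold = 0.01,
                                maxRank = 12L, gpRestarts = 4L,
                                acqStarts = 4L, simThreshold = 0.8) {
    stopifnot(is(gt, "GroundTruthSpace"))
    strategies <- match.arg(strategies, c("gpbo", "random"), several.ok = TRUE)
    ps <- gt@space
    rows <- list()
    for (seed in seeds) {
        for (strat in strategies) {
            experiments <- list()
            X <- lhsDesign(ps, batchSize,
                           seed = substreamSeed(seed, "design", 1L))
            for (it in seq_len(iterations)) {
                experiments <- c(experiments,
                                 .simulateBatch(gt, X, it, seed,
                                                idPrefix = strat))
                if (it == iterations) break
                if (strat == "random") {
                    X <- randomDesign(ps, batchSize,
                                      seed = substreamSeed(seed, "design",
                                                           it + 1L))
                } else {
                    sc <- scoreDataset(experiments, gt@smSpectra,
                                       relThreshold = relThreshold)
                    comp <- sc$compositions
                    Xtr <- toUnitCube(ps,
                                      as.matrix(comp[, dimNames(ps),
                                                     drop = FALSE]))
                    model <- fitSurrogate(Xtr, comp$score,
                                          nRestarts = gpRestarts,
                                          seed = substreamSeed(seed, "gp", it))
                    X <- suggestBatch(model, ps, batchSize = batchSize,
                                      kappa = kappa,
                                      seed = substreamSeed(seed, "batch", it),
                                      nStarts = acqStarts)
                }
            }
            disc <- .countDiscoveries(gt, experiments,
                                      relThreshold = relThreshold,
                                      maxRank = maxRank,
                                      seed = substreamSeed(seed, "nmf", 1L),
                                      simThreshold = simThreshold)
            rows[[length(rows) + 1L]] <- data.frame(
                seed = seed, strategy = strat, discovered = disc)
        }
    }
    perReplicate <- do.call(rbind, rows)
    means <- tapply(perReplicate$discovered, perReplicate$strategy, mean)
    list(perReplicate = perReplicate, means = means)
}
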