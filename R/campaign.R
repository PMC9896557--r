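#' @include AllClasses.R
NULL

.STATE_VERSION <- "1"

## one structured log line per operation: timestamp, op, details, and md5
## hashes of any files involved (audit trail for autonomous runs)
.logOp <- function(state, op, files = character(), info = list()) {
    hashes <- if (length(files)) {
        ex <- files[file.exists(files)]
        as.list(stats::setNames(unname(tools::md5sum(ex)), basename(ex)))
    } else NULL
    line <- jsonlite::toJSON(
        c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               op = op, iteration = state@iteration),
          info, if (length(hashes)) list(inputs = hashes)),
        auto_unbox = TRUE)
    cat(line, "\n", file = file.path(state@dir, "campaign.log"),
        append = TRUE, sep = "")
    invisible(NULL)
}

#' Initialize a campaign directory
#'
#' Creates the persistent state of an exploration campaign. All later
#' randomness (designs, GP restarts, NMF initializations, simulations)
#' flows from the single master seed via named substreams.
#'
#' @param dir campaign directory (created if needed).
#' @param space the [ProcessSpace-class] to explore.
#' @param config optional list of metric/GP/NMF settings
#'   (`relThreshold`, `topN`, `kappa`, `plateauTol`, ...).
#' @param seed master integer seed.
#' @return a [CampaignState-class], invisibly.
#' @export
initCampaign <- function(dir, space, config = list(), seed = 1L) {
    stopifnot(is(space, "ProcessSpace"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    state <- new("CampaignState", version = .STATE_VERSION, dir = dir,
                 space = space, config = config, seed = as.integer(seed),
                 iteration = 0L,
                 manifest = data.frame(), scores = data.frame())
    saveCampaign(state)
    .logOp(state, "init", info = list(seed = seed))
    invisible(state)
}

#' Persist / restore campaign state
#'
#' State is stored as JSON (`state.json` in the campaign directory) with a
#' version field checked on load; a reloaded campaign rescores
#' bit-identically because scoring is deterministic in the manifest.
#'
#' @param state a [CampaignState-class].
#' @return `saveCampaign`: the state, invisibly. `loadCampaign`: the
#'   restored [CampaignState-class].
#' @export
saveCampaign <- function(state) {
    stopifnot(is(state, "CampaignState"))
    d <- state@space@dimensions
    jsonlite::write_json(list(
        version = state@version, seed = state@seed,
        iteration = state@iteration,
        space = d, config = state@config,
        manifest = state@manifest, scores = state@scores),
        file.path(state@dir, "state.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    invisible(state)
}

#' @rdname saveCampaign
#' @param dir campaign directory to load from.
#' @export
loadCampaign <- function(dir) {
    path <- file.path(dir, "state.json")
    if (!file.exists(path)) stop("no state.json in ", dir)
    st <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(as.character(st$version), .STATE_VERSION))
        stop("unsupported state version: ", st$version)
    sp <- ProcessSpace(st$space$name, st$space$lower, st$space$upper,
                       if (is.null(st$space$step)) NA_real_ else st$space$step)
    asDf <- function(x) if (is.null(x) || !length(x)) data.frame()
                        else as.data.frame(x)
    new("CampaignState", version = as.character(st$version), dir = dir,
        space = sp, config = as.list(st$config), seed = as.integer(st$seed),
        iteration = as.integer(st$iteration),
        manifest = asDf(st$manifest), scores = asDf(st$scores))
}

## read every manifest row into a Spectrum; dimension columns are those
## matching the space
.manifestSpectra <- function(state, continueOnError = FALSE) {
    man <- state@manifest
    dims <- dimNames(state@space)
    out <- list(); errors <- character()
    for (i in seq_len(nrow(man))) {
        path <- man$file[i]
        if (!file.exists(path)) path <- file.path(state@dir, man$file[i])
        sp <- tryCatch({
            comp <- if (man$role[i] == "experiment")
                stats::setNames(as.numeric(man[i, dims]), dims)
            else numeric()
            readPeakTable(path, dialect = "csv",
                          sourceId = if (!is.null(man$id)) man$id[i]
                                     else basename(man$file[i]),
                          role = man$role[i], composition = comp,
                          temperature = if (man$role[i] == "experiment")
                              man$temperature[i] else NA_character_,
                          iteration = if (man$role[i] == "experiment")
                              as.integer(man$iteration[i]) else NA_integer_)
        }, error = function(e) e)
        if (inherits(sp, "error")) {
            msg <- paste0("row ", i, " (", man$file[i], "): ",
                          conditionMessage(sp))
            if (!continueOnError) stop(msg)
            errors <- c(errors, msg)
        } else out[[length(out) + 1L]] <- sp
    }
    list(spectra = out, errors = errors)
}

#' Score every manifest spectrum and update the campaign
#'
#' Appends `manifest` rows (if given) to the accumulated manifest, reads
#' all referenced spectra, recomputes the full two-part novelty scoring
#' over the accumulated dataset, and writes `novelty_records.csv`,
#' `composition_scores.csv` and `frequency_table.json` into the campaign
#' directory. Rerunning without new data reproduces identical outputs.
#'
#' @param state a [CampaignState-class].
#' @param manifest optional data.frame or CSV path with columns `file`,
#'   `role`, `temperature`, `iteration` and one column per space
#'   dimension; rows already present (same `file`) are ignored.
#' @param continueOnError log unreadable files and score the rest instead
#'   of stopping.
#' @return the updated state, invisibly; scores are in `state@scores`.
#' @export
cmdScore <- function(state, manifest = NULL, continueOnError = FALSE) {
    stopifnot(is(state, "CampaignState"))
    if (!is.null(manifest)) {
        if (is.character(manifest))
            manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
        if (nrow(state@manifest))
            manifest <- manifest[!manifest$file %in% state@manifest$file, ,
                                 drop = FALSE]
        state@manifest <- if (nrow(state@manifest))
            rbind(state@manifest, manifest) else manifest
    }
    if (!nrow(state@manifest)) stop("empty manifest; nothing to score")
    got <- .manifestSpectra(state, continueOnError)
    for (e in got$errors) warning(e)
    roles <- vapply(got$spectra, spectrumRole, "")
    exps <- got$spectra[roles == "experiment"]
    sms <- got$spectra[roles == "starting_material"]
    if (!length(sms)) stop("manifest contains no starting-material spectra")
    cfg <- state@config
    sc <- scoreDataset(exps, sms,
                       relThreshold = cfg$relThreshold %||% 0.01,
                       topN = cfg$topN %||% 5L)
    recPath <- file.path(state@dir, "novelty_records.csv")
    compPath <- file.path(state@dir, "composition_scores.csv")
    utils::write.csv(sc$records, recPath, row.names = FALSE)
    utils::write.csv(sc$compositions, compPath, row.names = FALSE)
    writeFrequencyTable(sc$frequencyTable,
                        file.path(state@dir, "frequency_table.json"))
    state@scores <- sc$compositions
    saveCampaign(state)
    .logOp(state, "score", files = c(recPath, compPath),
           info = list(nRecords = nrow(sc$records),
                       nErrors = length(got$errors)))
    invisible(state)
}

#' Suggest the next iteration's compositions
#'
#' Writes an n-row dispense CSV (`dispense_iter<N>.csv`) chosen by Latin
#' hypercube sampling (iteration 0 only), GP Bayesian optimization of the
#' stored composition scores, or uniform random sampling, then advances
#' the iteration counter. Deterministic for a given state and master
#' seed.
#'
#' @param state a [CampaignState-class].
#' @param strategy `"lhs"`, `"gpbo"` or `"random"`.
#' @param n batch size (default 48).
#' @return list: the updated `state` and the suggested `design` matrix.
#' @export
cmdSuggest <- function(state, strategy = c("lhs", "gpbo", "random"),
                       n = 48L) {
    stopifnot(is(state, "CampaignState"))
    strategy <- match.arg(strategy)
    it <- state@iteration
    seed <- substreamSeed(state@seed, "design", it + 1L)
    cfg <- state@config
    if (strategy == "lhs") {
        if (it != 0L) stop("LHS initialization is only allowed at iteration 0")
        X <- lhsDesign(state@space, n, seed = seed)
    } else if (strategy == "random") {
        X <- randomDesign(state@space, n, seed = seed)
    } else {
        if (!nrow(state@scores))
            stop("gpbo requires at least one scored iteration")
        dims <- dimNames(state@space)
        Xtr <- toUnitCube(state@space,
                          as.matrix(state@scores[, dims, drop = FALSE]))
        model <- fitSurrogate(Xtr, state@scores$score,
                              nRestarts = cfg$gpRestarts %||% 8L,
                              seed = substreamSeed(state@seed, "gp", it + 1L))
        X <- suggestBatch(model, state@space, batchSize = n,
                          kappa = cfg$kappa %||% 2,
                          seed = substreamSeed(state@seed, "batch", it + 1L),
                          nStarts = cfg$acqStarts %||% 8L)
    }
    state@iteration <- it + 1L
    path <- file.path(state@dir, sprintf("dispense_iter%d.csv",
                                         state@iteration))
    writeDispenseTable(X, path)
    saveCampaign(state)
    .logOp(state, "suggest", files = path,
           info = list(strategy = strategy, n = n))
    list(state = state, design = X)
}

#' Simulate spectra for a suggested design
#'
#' Plays the instrument's part in a synthetic campaign: simulates every
#' composition of `design` at each ground-truth temperature, writes the
#' spectra as CSV peak tables under `spectra/`, and returns manifest rows
#' (including the starting materials on first call) ready for
#' [cmdScore()].
#'
#' @param state a [CampaignState-class].
#' @param gt a [GroundTruthSpace-class].
#' @param design composition matrix (e.g. from [cmdSuggest()]).
#' @param iteration iteration tag for the rows (default: current).
#' @return manifest data.frame.
#' @export
cmdSimulate <- function(state, gt, design, iteration = state@iteration) {
    stopifnot(is(state, "CampaignState"), is(gt, "GroundTruthSpace"))
    specDir <- file.path(state@dir, "spectra")
    dir.create(specDir, showWarnings = FALSE)
    dims <- dimNames(state@space)
    rows <- list()
    for (sm in gt@smSpectra) {
        f <- file.path("spectra", paste0(sourceId(sm), ".csv"))
        full <- file.path(state@dir, f)
        if (!file.exists(full)) writePeakTable(sm, full)
        r <- data.frame(file = f, role = "starting_material",
                        temperature = NA, iteration = NA)
        r[dims] <- NA_real_
        rows[[length(rows) + 1L]] <- r
    }
    spectra <- .simulateBatch(gt, design, iteration,
                              seed = substreamSeed(state@seed, "simulate",
                                                   iteration),
                              idPrefix = "exp")
    for (sid in names(spectra)) {
        s <- spectra[[sid]]
        f <- file.path("spectra", paste0(sid, ".csv"))
        writePeakTable(s, file.path(state@dir, f))
        r <- data.frame(file = f, role = "experiment",
                        temperature = temperature(s), iteration = iteration)
        r[dims] <- as.list(composition(s))
        rows[[length(rows) + 1L]] <- r
    }
    man <- do.call(rbind, rows)
    manPath <- file.path(state@dir, sprintf("manifest_iter%d.csv", iteration))
    utils::write.csv(man, manPath, row.names = FALSE)
    .logOp(state, "simulate", files = manPath,
           info = list(nSpectra = length(spectra)))
    man
}

#' Deconvolute the accumulated spectra into archetypes
#'
#' For each requested scope (by default, each temperature separately;
#' optionally each iteration within each temperature), converts the
#' non-starting-material peaks into a binary barcode matrix, screens NMF
#' ranks, selects the plateau rank, factorizes, and writes the barcode
#' triplets, rank-error curve, serialized model and dominant-archetype
#' table into the campaign directory.
#'
#' @param state a scored [CampaignState-class].
#' @param temperature temperature label(s) to scope to (default: all
#'   present, each separately; `"all"` pools them).
#' @param perIteration additionally split each scope by iteration.
#' @param maxRank optional rank-screen ceiling.
#' @return named list of reports, one per scope, each with `rank`,
#'   `rankErrors`, `model` ([ArchetypeModel-class]) and `dominant`
#'   (data.frame).
#' @export
cmdDeconvolute <- function(state, temperature = NULL, perIteration = FALSE,
                           maxRank = NULL) {
    stopifnot(is(state, "CampaignState"))
    got <- .manifestSpectra(state)
    roles <- vapply(got$spectra, spectrumRole, "")
    exps <- got$spectra[roles == "experiment"]
    sms <- got$spectra[roles == "starting_material"]
    if (length(exps) < 2L) stop("need at least two scored experiments")
    cfg <- state@config
    relThreshold <- cfg$relThreshold %||% 0.01
    smUnion <- sort(unique(unlist(lapply(
        lapply(sms, applyNoiseThreshold, relThreshold), binPeaks))))

    temps <- vapply(exps, function(s) s@temperature, "")
    iters <- vapply(exps, function(s) s@iteration, NA_integer_)
    if (is.null(temperature)) temperature <- unique(temps)
    scopes <- list()
    for (tp in temperature) {
        sel <- if (tp == "all") rep(TRUE, length(exps)) else temps == tp
        if (perIteration) {
            for (it in sort(unique(iters[sel])))
                scopes[[paste0(tp, "_iter", it)]] <-
                    list(sel = sel & iters == it,
                         scope = list(temperature = tp, iteration = it))
        } else {
            scopes[[tp]] <- list(sel = sel, scope = list(temperature = tp))
        }
    }

    reports <- list()
    for (nm in names(scopes)) {
        sel <- scopes[[nm]]$sel
        if (sum(sel) < 2L) stop("scope '", nm, "' has fewer than 2 experiments")
        sub <- exps[sel]
        uniq <- lapply(sub, function(s)
            nonSmPeaks(binPeaks(applyNoiseThreshold(s, relThreshold)),
                       smUnion))
        names(uniq) <- vapply(sub, sourceId, "")
        B <- buildBarcodeMatrix(uniq, scope = scopes[[nm]]$scope)
        seed <- substreamSeed(state@seed, "nmf", sum(utf8ToInt(nm)))
        errs <- screenRanks(B, seed = seed, maxRank = maxRank)
        k <- max(2L, selectRank(errs, cfg$plateauTol %||% 0.05))
        model <- factorize(B, k, seed = seed, rankErrors = errs)
        dom <- dominantArchetype(model)
        stem <- file.path(state@dir, paste0("barcode_", nm))
        writeBarcodeMatrix(B, stem)
        utils::write.csv(data.frame(rank = as.integer(names(errs)),
                                    error = as.numeric(errs)),
                         file.path(state@dir,
                                   paste0("rank_errors_", nm, ".csv")),
                         row.names = FALSE)
        writeArchetypeModel(model,
                            file.path(state@dir,
                                      paste0("archetype_model_", nm, ".json")))
        utils::write.csv(dom,
                         file.path(state@dir,
                                   paste0("dominant_archetypes_", nm, ".csv")),
                         row.names = FALSE)
        reports[[nm]] <- list(rank = k, rankErrors = errs, model = model,
                              dominant = dom)
    }
    .logOp(state, "deconvolute",
           info = list(scopes = names(scopes),
                       ranks = vapply(reports, `[[`, 0L, "rank")))
    reports
}
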