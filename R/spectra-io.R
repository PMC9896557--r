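#' @include AllClasses.R
NULL

#' Read a peak table into a Spectrum
#'
#' Reads a centroided peak list from a two-column delimited text file
#' (m/z, intensity; header optional) or from a centroided mzML file. The
#' result is canonical: peaks sorted by m/z, exact duplicate m/z rows
#' merged by intensity sum.
#'
#' mzML files are read through \pkg{mzR} when it is installed; otherwise a
#' minimal built-in reader handles uncompressed 32/64-bit centroided mzML.
#'
#' @param path file to read.
#' @param dialect `"csv"`, `"tsv"` or `"mzml"`.
#' @param scan for mzML, which spectrum to take (default first).
#' @inheritParams Spectrum
#' @return a [Spectrum-class].
#' @seealso [writePeakTable()]
#' @export
readPeakTable <- function(path, dialect = c("csv", "tsv", "mzml"), scan = 1L,
                          sourceId = basename(path),
                          role = c("experiment", "starting_material"),
                          composition = numeric(),
                          temperature = NA_character_,
                          iteration = NA_integer_) {
    dialect <- match.arg(dialect)
    role <- match.arg(role)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "mzml") {
        pk <- .readMzml(path, scan)
    } else {
        sep <- if (dialect == "csv") "," else "\t"
        first <- readLines(path, n = 1L)
        if (!length(first)) stop("empty spectrum: no peaks in ", path)
        fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
        header <- any(is.na(suppressWarnings(as.numeric(fields[1:2]))))
        tab <- tryCatch(
            utils::read.table(path, sep = sep, header = header,
                              colClasses = "numeric"),
            error = function(e) stop("unparseable peak table '", path,
                                     "': ", conditionMessage(e)))
        if (ncol(tab) < 2L)
            stop("unparseable peak table '", path, "': need two columns")
        pk <- list(mz = tab[[1L]], intensity = tab[[2L]])
    }
    if (!length(pk$mz)) stop("empty spectrum: no peaks in ", path)
    Spectrum(pk$mz, pk$intensity, sourceId = sourceId, role = role,
             composition = composition, temperature = temperature,
             iteration = iteration)
}

## centroided mzML: mzR if present, else a small xml2-based reader for
## uncompressed zlib-free binary arrays
.readMzml <- function(path, scan = 1L) {
    if (requireNamespace("mzR", quietly = TRUE)) {
        h <- mzR::openMSfile(path)
        on.exit(mzR::close(h))
        p <- mzR::peaks(h, scan)
        return(list(mz = p[, 1L], intensity = p[, 2L]))
    }
    if (!requireNamespace("xml2", quietly = TRUE))
        stop("reading mzML requires either mzR or xml2")
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    spec <- xml2::xml_find_all(doc, ".//spectrum")
    if (length(spec) < scan) stop("mzML has no spectrum ", scan)
    arrays <- xml2::xml_find_all(spec[[scan]], ".//binaryDataArray")
    out <- list()
    for (arr in arrays) {
        cvs <- xml2::xml_find_all(arr, ".//cvParam")
        acc <- xml2::xml_attr(cvs, "accession")
        size <- if ("MS:1000523" %in% acc) 8L else 4L
        if ("MS:1000574" %in% acc)
            stop("compressed mzML binary arrays need mzR")
        b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
        vals <- readBin(jsonlite::base64_dec(gsub("\\s", "", b64)),
                        "double", n = 1e7, size = size)
        if ("MS:1000514" %in% acc) out$mz <- vals
        if ("MS:1000515" %in% acc) out$intensity <- vals
    }
    if (is.null(out$mz) || is.null(out$intensity))
        stop("mzML spectrum lacks m/z or intensity arrays")
    out
}

#' Write a Spectrum as a canonical CSV peak table
#'
#' @param s a [Spectrum-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(s, path) {
    stopifnot(is(s, "Spectrum"))
    utils::write.csv(peakTable(s), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Remove peaks below a relative noise threshold
#'
#' Retains exactly the peaks whose intensity is at least
#' `relThreshold` times the base-peak (maximum) intensity. The threshold is
#' relative so the operation is invariant to instrument intensity scaling.
#'
#' @param s a [Spectrum-class].
#' @param relThreshold fraction of base-peak intensity in [0, 1); default 1%.
#' @return the thresholded [Spectrum-class].
#' @export
applyNoiseThreshold <- function(s, relThreshold = 0.01) {
    stopifnot(is(s, "Spectrum"))
    if (relThreshold < 0 || relThreshold >= 1)
        stop("relThreshold must lie in [0, 1)")
    if (!nPeaks(s)) stop("empty spectrum")
    keep <- intensity(s) >= relThreshold * max(intensity(s))
    s@peaks <- s@peaks[keep, , drop = FALSE]
    rownames(s@peaks) <- NULL
    validObject(s)
    s
}

#' Binned m/z of the n most intense peaks
#'
#' Selects the `n` highest-intensity peaks (ties broken toward lower m/z)
#' and returns their unit-resolution bins. If the spectrum has fewer than
#' `n` peaks, all are used.
#'
#' @param s a [Spectrum-class] (non-empty).
#' @param n number of peaks (default 5, the top-peak window used by the
#'   novelty metric).
#' @return sorted integer vector of bins (a peak set).
#' @export
topNPeaks <- function(s, n = 5L) {
    stopifnot(is(s, "Spectrum"))
    .assertScalarCount(n)
    if (!nPeaks(s)) stop("empty spectrum")
    o <- order(-intensity(s), mz(s))
    sel <- o[seq_len(min(n, nPeaks(s)))]
    sort(unique(as.integer(.roundHalfUp(mz(s)[sel]))))
}

#' Bin all peaks of a spectrum to unit resolution
#'
#' Each m/z is rounded half-up to the nearest integer and duplicates are
#' collapsed; peak identity throughout the pipeline is this nominal-mass
#' bin.
#'
#' @param s a [Spectrum-class] (non-empty).
#' @return sorted integer vector of bins (a peak set).
#' @export
binPeaks <- function(s) {
    stopifnot(is(s, "Spectrum"))
    if (!nPeaks(s)) stop("empty spectrum")
    sort(unique(as.integer(.roundHalfUp(mz(s)))))
}

#' Export a peak set as JSON
#'
#' @param bins integer vector of binned m/z.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeakSet <- function(bins, path) {
    jsonlite::write_json(sort(unique(as.integer(bins))), path)
    invisible(path)
}
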