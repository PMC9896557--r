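#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Accessors for the S4 classes in ChemProspector. Slot access via `@` is
#' considered internal; use these instead.
#'
#' @param object an object of the appropriate class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("spectrumRole", function(object) standardGeneric("spectrumRole"))

#' @rdname accessors
#' @export
setGeneric("composition", function(object) standardGeneric("composition"))

#' @rdname accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))

#' @rdname accessors
#' @export
setGeneric("iteration", function(object) standardGeneric("iteration"))

#' @rdname accessors
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))

#' @rdname accessors
#' @export
setGeneric("dimNames", function(object) standardGeneric("dimNames"))

#' @rdname accessors
#' @export
setGeneric("nDims", function(object) standardGeneric("nDims"))

#' @rdname accessors
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))

#' @rdname accessors
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))

#' @rdname accessors
#' @export
setGeneric("peakCounts", function(object) standardGeneric("peakCounts"))

#' @rdname accessors
#' @export
setGeneric("datasetSize", function(object) standardGeneric("datasetSize"))

#' @rdname accessors
#' @export
setGeneric("barcodes", function(object) standardGeneric("barcodes"))

#' @rdname accessors
#' @export
setGeneric("barcodeScope", function(object) standardGeneric("barcodeScope"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("coefficientMatrix", function(object) standardGeneric("coefficientMatrix"))

#' @rdname accessors
#' @export
setGeneric("modelRank", function(object) standardGeneric("modelRank"))

#' @rdname accessors
#' @export
setGeneric("rankErrors", function(object) standardGeneric("rankErrors"))

#' @rdname accessors
#' @export
setGeneric("hyperParameters", function(object) standardGeneric("hyperParameters"))

#' @rdname accessors
#' @export
setGeneric("trainingData", function(object) standardGeneric("trainingData"))
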