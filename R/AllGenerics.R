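#' @importFrom methods setGeneric setClass setMethod setValidity new validObject is slot
NULL

#' Wavenumber axis of a spectral object
#'
#' @param x an object carrying a wavenumber axis.
#' @return Numeric vector of wavenumbers in cm^-1, strictly descending.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Intensity matrix of a spectral object
#'
#' @param x an object carrying spectral intensities.
#' @return Numeric matrix, wavenumbers in rows (descending), samples in columns.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Processing history of a spectral object
#'
#' @param x an object with a recorded processing state.
#' @return Character vector of processing steps, in order of application.
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' Subtract a scaled reference spectrum
#'
#' @param x object holding sample spectra.
#' @param reference the reference (e.g. buffer) spectrum.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("subtractReference",
           function(x, reference, ...) standardGeneric("subtractReference"))

#' Savitzky-Golay smoothing / differentiation
#'
#' @param x object holding spectra.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("savgolDerivative", function(x, ...) standardGeneric("savgolDerivative"))

#' Euclidean (vector) normalization
#'
#' @param x object holding spectra.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("vectorNormalize", function(x, ...) standardGeneric("vectorNormalize"))

#' Min/max normalization anchored on a stable band
#'
#' @param x object holding spectra.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("minmaxNormalize", function(x, ...) standardGeneric("minmaxNormalize"))

#' Extract a wavenumber region
#'
#' @param x object holding spectra.
#' @param region numeric length-2 closed wavenumber interval (cm^-1), any order.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("extractRegion", function(x, region, ...) standardGeneric("extractRegion"))

#' Mean-center spectra across samples
#'
#' @param x object holding spectra.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("meanCenter", function(x, ...) standardGeneric("meanCenter"))

#' Principal-component scores
#'
#' @param x a fitted decomposition model.
#' @return Numeric matrix of scores, samples in rows.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Principal-component loadings
#'
#' @param x a fitted decomposition model.
#' @return Numeric matrix of loadings, variables in rows.
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' Explained variance per component
#'
#' @param x a fitted decomposition model.
#' @return Numeric vector of percentages, non-increasing.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' Confusion matrix of a classifier
#'
#' @param x a fitted classifier.
#' @param which `"heldout"` or `"all"`.
#' @export
setGeneric("confusionMatrix",
           function(x, which = c("heldout", "all")) standardGeneric("confusionMatrix"))
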