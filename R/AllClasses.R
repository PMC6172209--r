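#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom SummarizedExperiment `assays<-` `colData<-`
#' @importFrom S4Vectors DataFrame metadata `metadata<-` SimpleList
NULL

# ---------------------------------------------------------------------------
# IRSpectraSet: a set of spectra on a common wavenumber grid
# ---------------------------------------------------------------------------

#' Container for a set of IR spectra on a common wavenumber grid
#'
#' `IRSpectraSet` extends [SummarizedExperiment::SummarizedExperiment]:
#' rows are wavenumber variables (stored in `rowData(x)$wavenumber`,
#' strictly descending per FTIR convention), columns are samples with the
#' experimental design in `colData` (`sample_id`, `cell_line`, `dose`,
#' `bio_rep`, `tech_rep`). The single assay `"intensity"` holds absorbance
#' (or derived) values; the ordered list of preprocessing steps applied so
#' far is kept in `metadata(x)$processing` and queried with
#' [processingLog()].
#'
#' @export
setClass("IRSpectraSet", contains = "SummarizedExperiment")

setValidity("IRSpectraSet", function(object) {
  wn <- rowData(object)$wavenumber
  if (is.null(wn))
    return("rowData must contain a 'wavenumber' column")
  if (!is.numeric(wn) || anyNA(wn))
    return("wavenumbers must be numeric and non-missing")
  if (length(wn) > 1 && any(diff(wn) >= 0))
    return("wavenumbers must be strictly descending")
  if (!"intensity" %in% names(assays(object)))
    return("assay 'intensity' is required")
  if (anyNA(assay(object, "intensity")))
    return("intensity values must be non-missing")
  pr <- metadata(object)$processing
  if (!is.null(pr) && !is.character(pr))
    return("metadata(x)$processing must be a character vector")
  TRUE
})

#' Construct an IRSpectraSet
#'
#' @param intensity numeric matrix, wavenumbers in rows (descending), samples
#'   in columns.
#' @param wavenumber numeric vector of wavenumbers (cm^-1), strictly
#'   descending, one per row of `intensity`.
#' @param sampleData `data.frame` of per-sample metadata (one row per column
#'   of `intensity`). A `sample_id` column is added if absent.
#' @param processing character vector of already-applied processing steps.
#' @param metadata named list of additional metadata (e.g. the buffer
#'   reference spectrum under `reference`).
#' @return An [IRSpectraSet-class] object.
#' @examples
#' wn <- seq(4000, 650, by = -1)
#' m <- matrix(rnorm(length(wn) * 2, 0.5, 0.01), ncol = 2)
#' s <- IRSpectraSet(m, wn, data.frame(dose = c(0, 0.5)))
#' s
#' @export
IRSpectraSet <- function(intensity, wavenumber,
                         sampleData = NULL,
                         processing = "raw",
                         metadata = list()) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(wavenumber))
    stop("nrow(intensity) must equal length(wavenumber)")
  n <- ncol(intensity)
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = seq_len(n))
  if (nrow(sampleData) != n)
    stop("sampleData must have one row per spectrum")
  if (is.null(sampleData$sample_id))
    sampleData$sample_id <- sprintf("S%03d", seq_len(n))
  colnames(intensity) <- sampleData$sample_id
  md <- c(list(processing = processing), metadata)
  se <- SummarizedExperiment(
    assays  = SimpleList(intensity = intensity),
    rowData = DataFrame(wavenumber = as.numeric(wavenumber)),
    colData = DataFrame(sampleData, row.names = sampleData$sample_id),
    metadata = md)
  new("IRSpectraSet", se)
}

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "IRSpectraSet",
          function(x) as.numeric(rowData(x)$wavenumber))

#' @rdname intensities
#' @export
setMethod("intensities", "IRSpectraSet",
          function(x) assay(x, "intensity"))

#' @rdname processingLog
#' @export
setMethod("processingLog", "IRSpectraSet",
          function(x) as.character(metadata(x)$processing))

# append a processing step; internal
.addStep <- function(x, step, intensity = NULL) {
  if (!is.null(intensity)) {
    dimnames(intensity) <- dimnames(assay(x, "intensity"))
    assays(x)$intensity <- intensity
  }
  metadata(x)$processing <- c(processingLog(x), step)
  x
}

.hasStep <- function(x, step) any(startsWith(processingLog(x), step))

setMethod("show", "IRSpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("IRSpectraSet: %d spectra x %d wavenumbers (%g..%g cm-1)\n",
              ncol(object), nrow(object), wn[1], wn[length(wn)]))
  cd <- colData(object)
  for (f in intersect(c("cell_line", "dose"), colnames(cd)))
    cat(sprintf("  %s: %s\n", f, paste(unique(cd[[f]]), collapse = ", ")))
  cat("  processing:", paste(processingLog(object), collapse = " -> "), "\n")
})

# ---------------------------------------------------------------------------
# EffectModel: dose-dependent perturbation of a base band profile
# ---------------------------------------------------------------------------

#' Dose-effect model for the spectrum generator
#'
#' Describes, for one cell line, how DMSO dose perturbs the base band
#' profile: multiplicative amplitude factors per marker band and dose, the
#' fraction of alpha-helix amide I intensity converted to beta-sheet, plus
#' nuisance parameters (baseline drift, residual free-water band at
#' 2125 cm^-1, biological-replicate jitter, noise).
#'
#' @slot cellLine character label.
#' @slot doses numeric vector of tabulated doses (percent v/v), ascending,
#'   containing 0.
#' @slot multipliers numeric matrix `length(doses)` x bands; row for dose 0
#'   is all 1. Doses between tabulated values are linearly interpolated.
#' @slot conversion numeric vector, per-dose alpha-to-beta conversion
#'   fraction in `[0,1]`; 0 at dose 0.
#' @slot baseline numeric named vector `c(offset, slope, curvature)` of the
#'   smooth baseline in absorbance units over the normalized grid coordinate.
#' @slot waterAmplitude absorbance amplitude of the residual free-water band
#'   centred at 2125 cm^-1 (FWHM 160 cm^-1).
#' @slot jitterSD sdlog of the log-normal biological-replicate amplitude
#'   factor (one factor per replicate, shared by all bands).
#' @slot noiseSD standard deviation of i.i.d. gaussian noise (absorbance).
#' @export
setClass("EffectModel",
  representation(cellLine = "character", doses = "numeric",
                 multipliers = "matrix", conversion = "numeric",
                 baseline = "numeric", waterAmplitude = "numeric",
                 jitterSD = "numeric", noiseSD = "numeric"))

setValidity("EffectModel", function(object) {
  d <- object@doses
  if (length(d) < 1 || is.unsorted(d, strictly = TRUE) || !0 %in% d)
    return("doses must be strictly ascending and include 0")
  if (nrow(object@multipliers) != length(d))
    return("multipliers must have one row per dose")
  if (any(object@multipliers < 0))
    return("amplitude multipliers must be >= 0")
  if (any(abs(object@multipliers[d == 0, ]) != 1))
    return("multipliers at dose 0 must all be 1")
  cv <- object@conversion
  if (length(cv) != length(d) || any(cv < 0 | cv > 1) || cv[d == 0] != 0)
    return("conversion must be in [0,1] with value 0 at dose 0")
  if (object@noiseSD < 0 || object@jitterSD < 0 || object@waterAmplitude < 0)
    return("noiseSD, jitterSD and waterAmplitude must be >= 0")
  TRUE
})

setMethod("show", "EffectModel", function(object) {
  cat(sprintf("EffectModel '%s': doses {%s}%% v/v, %d perturbed bands\n",
              object@cellLine, paste(object@doses, collapse = ", "),
              ncol(object@multipliers)))
  cat(sprintf("  conversion: %s; noise sd %.4g; jitter sdlog %.4g\n",
              paste(object@conversion, collapse = "/"),
              object@noiseSD, object@jitterSD))
})

# ---------------------------------------------------------------------------
# PCAModel
# ---------------------------------------------------------------------------

#' NIPALS principal-component model
#'
#' @slot scores samples x k score matrix.
#' @slot loadings variables x k orthonormal loading matrix.
#' @slot explainedVariance percent of total (centered) sum of squares per
#'   component, non-increasing.
#' @slot center column means used for centering.
#' @slot totalSS total centered sum of squares of the training matrix.
#' @slot iterations iterations used per component.
#' @slot converged logical per component.
#' @export
setClass("PCAModel",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", center = "numeric",
                 totalSS = "numeric", iterations = "integer",
                 converged = "logical"))

setValidity("PCAModel", function(object) {
  k <- ncol(object@scores)
  if (ncol(object@loadings) != k)
    return("scores and loadings must agree on component count")
  if (length(object@explainedVariance) != k)
    return("one explained-variance entry per component required")
  TRUE
})

#' @rdname scores
#' @export
setMethod("scores", "PCAModel", function(x) x@scores)

#' @rdname pcLoadings
#' @export
setMethod("pcLoadings", "PCAModel", function(x) x@loadings)

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "PCAModel", function(x) x@explainedVariance)

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components, %d samples x %d variables\n",
              ncol(object@scores), nrow(object@scores), nrow(object@loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", object@explainedVariance), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# LDAModel
# ---------------------------------------------------------------------------

#' Distance-based discriminant model on PC scores
#'
#' Classification by smallest Mahalanobis distance to the class means,
#' under either the pooled within-class covariance (`kind = "linear"`) or
#' per-class covariances (`kind = "mahalanobis"`).
#'
#' @slot kind `"linear"` or `"mahalanobis"`.
#' @slot classes class labels.
#' @slot classMeans classes x m matrix of class means in score space.
#' @slot pooledCov pooled within-class covariance (m x m).
#' @slot classCovs list of per-class covariance matrices (mahalanobis kind).
#' @slot priors class prior probabilities, sum to 1.
#' @slot ridge ridge constant added to covariance diagonals (0 if none).
#' @slot trainIdx indices of training samples.
#' @slot predictions data.frame with sample index, true and predicted label,
#'   and train/test role.
#' @slot confusionHeldout,confusionAll contingency tables (true x predicted).
#' @slot accuracyHeldout,accuracyAll percent correct.
#' @export
setClass("LDAModel",
  representation(kind = "character", classes = "character",
                 classMeans = "matrix", pooledCov = "matrix",
                 classCovs = "list", priors = "numeric", ridge = "numeric",
                 trainIdx = "integer", predictions = "data.frame",
                 confusionHeldout = "table", confusionAll = "table",
                 accuracyHeldout = "numeric", accuracyAll = "numeric"))

setValidity("LDAModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-8)
    return("class priors must sum to 1")
  if (!isSymmetric(unname(object@pooledCov), tol = 1e-8))
    return("pooled covariance must be symmetric")
  TRUE
})

#' @rdname confusionMatrix
#' @export
setMethod("confusionMatrix", "LDAModel", function(x, which = c("heldout", "all")) {
  which <- match.arg(which)
  if (which == "heldout") x@confusionHeldout else x@confusionAll
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel (%s classifier), %d classes: %s\n", object@kind,
              length(object@classes), paste(object@classes, collapse = ", ")))
  cat(sprintf("  held-out accuracy %.1f%% (n=%d), all-sample accuracy %.1f%%\n",
              object@accuracyHeldout,
              sum(object@confusionHeldout), object@accuracyAll))
})
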