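# Preprocessing: scaled reference subtraction with free-water flattening,
# Savitzky-Golay smoothing/derivatives, vector and min/max normalization,
# region extraction.

# indices of grid points inside a closed wavenumber interval (any order)
.regionIdx <- function(wn, region) {
  stopifnot(is.numeric(region), length(region) == 2)
  lo <- min(region); hi <- max(region)
  which(wn >= lo & wn <= hi)
}

#' @describeIn subtractReference Subtract a scaled buffer reference.
#'
#' Returns `x - k * reference` per sample, with `k` chosen per sample to
#' flatten the residual free-water region: `k` minimizes the sum of squared
#' residuals of the difference spectrum from a straight line fitted within
#' `flattenWindow` (default 2200-2050 cm^-1, bracketing the 2125 cm^-1 free
#' water band). Closed form: with `P` the projector removing the best-fit
#' line over the window, `k = <P y, P r> / ||P r||^2`. The fitted `k` is
#' stored in `colData(x)$subtraction_k`.
#'
#' @param flattenWindow length-2 wavenumber interval used for flattening.
#' @export
setMethod("subtractReference", "IRSpectraSet",
function(x, reference, flattenWindow = c(2200, 2050), ...) {
  wn <- wavenumbers(x)
  if (is(reference, "IRSpectraSet")) {
    if (!isTRUE(all.equal(wn, wavenumbers(reference))))
      stop("sample and reference are on different wavenumber grids")
    reference <- intensities(reference)[, 1]
  }
  if (length(reference) != length(wn))
    stop("sample and reference are on different wavenumber grids")
  if (.hasStep(x, "background_subtracted"))
    stop("spectra are already background-subtracted")
  idx <- .regionIdx(wn, flattenWindow)
  if (length(idx) < 3) stop("flatten window contains too few grid points")
  r <- reference[idx]
  if (all(r == 0)) stop("reference is all zero within the flatten window")
  X <- cbind(1, wn[idx])
  P <- diag(length(idx)) - X %*% solve(crossprod(X), t(X))
  Pr <- P %*% r
  den <- sum(Pr^2)
  if (den < .Machine$double.eps * length(idx))
    stop("reference is linear (degenerate) within the flatten window")
  Y <- intensities(x)
  k <- as.numeric(crossprod(Pr, P %*% Y[idx, , drop = FALSE])) / den
  out <- Y - outer(reference, k)
  x <- .addStep(x, "background_subtracted", out)
  colData(x)$subtraction_k <- k
  x
})

# Savitzky-Golay weight row: fit a polynomial of order p over the given
# offsets (in x units) and return the d-th derivative evaluated at 0.
.sgWeights <- function(offsets, p, d) {
  V <- outer(offsets, 0:p, "^")
  C <- solve(crossprod(V), t(V))       # (p+1) x n coefficient solver
  factorial(d) * C[d + 1, ]
}

# core filter on a matrix (columns = spectra), x spacing `h` assumed uniform
.savgolMatrix <- function(Y, h, window, p, d) {
  n <- nrow(Y)
  half <- (window - 1) / 2
  off <- (-half:half) * h
  w <- .sgWeights(off, p, d)
  out <- matrix(0, n, ncol(Y))
  # interior: convolution
  for (j in seq_len(ncol(Y)))
    out[(half + 1):(n - half), j] <-
      as.numeric(stats::filter(Y[, j], rev(w), sides = 2))[(half + 1):(n - half)]
  # edges: polynomial fit on the truncated window, derivative at the point
  for (i in c(seq_len(half), (n - half + 1):n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    we <- .sgWeights(((lo:hi) - i) * h, min(p, hi - lo), d)
    out[i, ] <- we %*% Y[lo:hi, , drop = FALSE]
  }
  out
}

#' @describeIn savgolDerivative Savitzky-Golay smoothing (deriv = 0) or
#' second derivative (deriv = 2) with respect to wavenumber, computed by
#' local polynomial least squares on a moving window; edge points are fitted
#' on the truncated window. Defaults (9-point window, order 3) are the
#' common choice for 4 cm^-1 FTIR data exported on a 1 cm^-1 grid.
#'
#' @param windowPoints odd window length in grid points (> `polyOrder`).
#' @param polyOrder polynomial order of the local fit.
#' @param deriv derivative order, 0 or 2.
#' @export
setMethod("savgolDerivative", "IRSpectraSet",
function(x, windowPoints = 9, polyOrder = 3, deriv = 2, ...) {
  stopifnot(deriv %in% c(0, 2))
  n <- nrow(x)
  if (windowPoints %% 2 == 0 || windowPoints <= polyOrder)
    stop("windowPoints must be odd and greater than polyOrder")
  if (windowPoints > n) stop("window longer than the spectrum")
  if (deriv > polyOrder) stop("deriv must not exceed polyOrder")
  wn <- wavenumbers(x)
  h <- wn[2] - wn[1]                  # negative for descending grids
  out <- .savgolMatrix(intensities(x), h, windowPoints, polyOrder, deriv)
  step <- if (deriv == 2)
    sprintf("second_derivative(w=%d,p=%d)", windowPoints, polyOrder)
  else sprintf("sg_smoothed(w=%d,p=%d)", windowPoints, polyOrder)
  .addStep(x, step, out)
})

#' @describeIn vectorNormalize Divide each spectrum by its Euclidean norm.
#' With `region` given, the norm is computed over that wavenumber interval
#' only (the whole spectrum is still rescaled), so the output has unit norm
#' over the region.
#'
#' @param region optional length-2 wavenumber interval over which the norm
#'   is computed; default the full grid.
#' @export
setMethod("vectorNormalize", "IRSpectraSet",
function(x, region = NULL, ...) {
  wn <- wavenumbers(x)
  idx <- if (is.null(region)) seq_along(wn) else .regionIdx(wn, region)
  if (!length(idx)) stop("normalization region does not overlap the grid")
  Y <- intensities(x)
  nrm <- sqrt(colSums(Y[idx, , drop = FALSE]^2))
  if (any(nrm == 0))
    stop("zero-norm spectrum: cannot vector-normalize sample(s) ",
         paste(which(nrm == 0), collapse = ", "))
  .addStep(x, "vector_normalized", sweep(Y, 2, nrm, "/"))
})

#' @describeIn minmaxNormalize Affine rescale per spectrum so that its
#' global minimum maps to 0 and its maximum within `anchorWindow` (default
#' 1700-1480 cm^-1, the amide I/II envelope) maps to 1.
#'
#' @param anchorWindow length-2 wavenumber interval holding the anchor peak.
#' @export
setMethod("minmaxNormalize", "IRSpectraSet",
function(x, anchorWindow = c(1700, 1480), ...) {
  wn <- wavenumbers(x)
  idx <- .regionIdx(wn, anchorWindow)
  if (!length(idx)) stop("anchor window does not overlap the grid")
  Y <- intensities(x)
  lo <- apply(Y, 2, min)
  hi <- apply(Y[idx, , drop = FALSE], 2, max)
  if (any(hi - lo <= 0))
    stop("flat spectrum: min/max normalization is degenerate for sample(s) ",
         paste(which(hi - lo <= 0), collapse = ", "))
  .addStep(x, "minmax_normalized", sweep(sweep(Y, 2, lo, "-"), 2, hi - lo, "/"))
})

#' @describeIn extractRegion Keep every grid point inside the closed
#' interval `region` (both endpoints included when on-grid); descending
#' order is preserved.
#' @export
setMethod("extractRegion", "IRSpectraSet",
function(x, region, ...) {
  idx <- .regionIdx(wavenumbers(x), region)
  if (!length(idx))
    stop("region [", min(region), ", ", max(region),
         "] does not overlap the wavenumber grid")
  x[idx, ]
})

#' @describeIn meanCenter Subtract, at every wavenumber, the mean across
#' samples (the column mean of the samples x variables data matrix).
#' @export
setMethod("meanCenter", "IRSpectraSet",
function(x, ...) {
  Y <- intensities(x)
  .addStep(x, "mean_centered", Y - rowMeans(Y))
})
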