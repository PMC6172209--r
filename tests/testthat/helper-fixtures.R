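# shared fixtures: tiny spectra built in code

# wrap a plain matrix (rows = wavenumbers, descending) as an IRSpectraSet
toySet <- function(values, wn = NULL, dose = NULL, processing = "raw") {
  values <- as.matrix(values)
  if (is.null(wn)) wn <- seq(100 + nrow(values) - 1, 100)
  sd <- if (is.null(dose)) NULL else data.frame(dose = dose)
  IRSpectraSet(values, wn, sd, processing = processing)
}

# one-gaussian spectrum set on the default grid
gaussianSet <- function(center, fwhm, amplitude, grid = wavenumberGrid()) {
  tr <- evaluateBand(list(center = center, fwhm = fwhm, amplitude = amplitude),
                     grid)
  toySet(matrix(tr, ncol = 1), wn = grid)
}

# analytic second derivative of a gaussian band w.r.t. wavenumber
gaussD2 <- function(nu, center, fwhm, amplitude) {
  s2 <- fwhm^2 / (8 * log(2))
  amplitude * exp(-(nu - center)^2 / (2 * s2)) *
    ((nu - center)^2 / s2^2 - 1 / s2)
}

# noise- and jitter-free effect model for deterministic checks
quietEffect <- function(cellLine = "HCT116", ...)
  defaultEffectModel(cellLine, noiseSD = 0, jitterSD = 0, ...)
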