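# marker-band quantification and derived macromolecular statistics

test_that("bandIntensity reads absorbance maxima and 2nd-derivative minima", {
  s <- vectorNormalize(gaussianSet(1172, 10, 0.4))
  asg <- data.frame(band = "chol_ester", center = 1172, window_high = 1176,
                    window_low = 1168, source = "absorbance")
  r <- bandIntensity(s, asg)
  expect_equal(r$peak_wavenumber, 1172)
  # vector-normalized peak height = amplitude / norm of the trace
  tr <- evaluateBand(list(center = 1172, fwhm = 10, amplitude = 0.4),
                     wavenumberGrid())
  expect_equal(r$intensity, 0.4 / sqrt(sum(tr^2)))

  # second-derivative source: magnitude of the negative lobe at the center,
  # cross-checked against the analytic gaussian second derivative
  sd <- vectorNormalize(savgolDerivative(gaussianSet(1172, 10, 0.4), 9, 3, 2))
  asg$source <- "second_derivative"
  r2 <- bandIntensity(sd, asg)
  expect_equal(r2$peak_wavenumber, 1172)
  # SG smoothing attenuates the narrow negative lobe by a few percent
  exact <- -gaussD2(wavenumberGrid(), 1172, 10, 0.4)
  expect_equal(r2$intensity, max(exact) / sqrt(sum(exact^2)), tolerance = 0.05)
})

test_that("flat spectra give zero intensity with the tie broken to center", {
  s <- toySet(matrix(rep(0, 3351), ncol = 1), wn = wavenumberGrid(),
              processing = "vector_normalized")
  asg <- data.frame(band = "zdna", center = 1066, window_high = 1071,
                    window_low = 1061, source = "absorbance")
  r <- bandIntensity(s, asg)
  expect_equal(r$peak_wavenumber, 1066)
  expect_equal(r$intensity, 0)
  asg$source <- "second_derivative"
  expect_equal(bandIntensity(s, asg)$intensity, 0)
})

test_that("percentOfUntreated pins the untreated mean at exactly 100", {
  tbl <- data.frame(sample_id = paste0("s", 1:4),
                    dose = c(0, 0, 0, 1), band = "zdna",
                    intensity = c(2, 2, 2, 1))
  out <- percentOfUntreated(tbl)
  expect_equal(out$percent, c(100, 100, 100, 50))
  # doubling raw intensities leaves percent unchanged
  tbl2 <- tbl; tbl2$intensity <- tbl2$intensity * 2
  expect_equal(percentOfUntreated(tbl2)$percent, out$percent)
  # untreated mean is exactly 100 for every band of a full pipeline run
  d <- sampleDesign("HCT116", doses = c(0, 0.5), bioReps = 2, techReps = 2,
                    seed = 2)
  full <- percentOfUntreated(quantifyBands(generateExperiment(d)))
  ut <- full[full$dose == 0, ]
  for (b in unique(ut$band))
    expect_equal(mean(ut$percent[ut$band == b]), 100, tolerance = 1e-12)
  expect_error(percentOfUntreated(tbl[tbl$dose > 0, ]), "no untreated")
})

test_that("Z-DNA enhancement fold recovers the generator multiplier exactly", {
  # noise off, only the Z band scaled: fold = multiplier to 1e-6 relative
  for (f in c(1.2, 2.0)) {
    eff <- effectModel("HCT116", doses = c(0, 1.5),
                       multipliers = rbind(c(zdna = 1), c(zdna = f)),
                       conversion = c(0, 0), jitterSD = 0, noiseSD = 0)
    d <- sampleDesign("HCT116", doses = c(0, 1.5), bioReps = 1, techReps = 1,
                      seed = 1)
    tbl <- quantifyBands(generateExperiment(d, effects = eff))
    z <- zdnaEnhancementRatio(tbl)
    expect_equal(z$fold_change[z$dose == 0], 1)
    expect_equal(z$fold_change[z$dose == 1.5], f, tolerance = 1e-6)
  }
})

test_that("Z fold change is strictly increasing in the generator multiplier", {
  folds <- vapply(c(1.2, 1.6, 2.0), function(f) {
    eff <- effectModel("HCT116", doses = c(0, 1.5),
                       multipliers = rbind(c(zdna = 1), c(zdna = f)),
                       conversion = c(0, 0), jitterSD = 0, noiseSD = 0)
    d <- sampleDesign("HCT116", doses = c(0, 1.5), bioReps = 1, techReps = 1,
                      seed = 1)
    z <- zdnaEnhancementRatio(quantifyBands(generateExperiment(d, effects = eff)))
    z$fold_change[z$dose == 1.5]
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
})

test_that("zdnaEnhancementRatio rejects a vanishing denominator", {
  tbl <- data.frame(sample_id = rep(paste0("s", 1:2), each = 3),
                    dose = rep(c(0, 1), each = 3),
                    band = rep(c("zdna", "adna", "bdna"), 2),
                    intensity = c(1, 0, 0, 2, 0, 0))
  expect_error(zdnaEnhancementRatio(tbl), "undefined")
})

test_that("lipid unsaturation ratio follows the percent arithmetic", {
  # equal percent intensities of the four lipid bands -> ratio 25%
  tbl <- data.frame(sample_id = "s1", dose = 0,
                    band = c("olefinic", "ch2_antisym", "ch2_sym", "chol_ester"),
                    intensity = 1, percent = 100)
  r <- lipidUnsaturationSummary(tbl)
  expect_equal(r$olefinic_total_mean, 25)
  # olefinic multiplier 1.2, others 1: ratio scales by 1.2 / (1 + 0.2/4)
  eff <- effectModel("HCT116", doses = c(0, 0.5),
                     multipliers = rbind(c(olefinic = 1), c(olefinic = 1.2)),
                     conversion = c(0, 0), jitterSD = 0, noiseSD = 0)
  d <- sampleDesign("HCT116", doses = c(0, 0.5), bioReps = 1, techReps = 1,
                    seed = 1)
  full <- percentOfUntreated(quantifyBands(generateExperiment(d, effects = eff)))
  rl <- lipidUnsaturationSummary(full)
  # percent values carry the (small) whole-spectrum norm shift; the ratio
  # below is norm-free
  expect_equal(rl$olefinic_mean[rl$dose == 0.5], 120, tolerance = 0.005)
  expect_equal(rl$olefinic_total_mean[rl$dose == 0.5] /
                 rl$olefinic_total_mean[rl$dose == 0],
               1.2 / (1 + 0.2 / 4), tolerance = 1e-4)
})

test_that("scaling all four lipid bands leaves the ratio unchanged", {
  tbl <- data.frame(sample_id = rep(c("s1", "s2"), each = 4),
                    dose = c(rep(0, 4), rep(1, 4)),
                    band = rep(c("olefinic", "ch2_antisym", "ch2_sym",
                                 "chol_ester"), 2),
                    intensity = c(1, 3, 2, 0.5, 3, 9, 6, 1.5))
  tbl$percent <- c(100, 100, 100, 100, 300, 300, 300, 300)
  r <- lipidUnsaturationSummary(tbl)
  expect_equal(r$olefinic_total_mean[1], r$olefinic_total_mean[2])
})

test_that("secondary structure conversion recovers the generator parameter", {
  # noise off: conversion parameter recovered within the spec's 2-point band
  for (cv in c(0.15, 0.40)) {
    eff <- effectModel("HCT116", doses = c(0, 1),
                       multipliers = rbind(c(zdna = 1), c(zdna = 1)),
                       conversion = c(0, cv), jitterSD = 0, noiseSD = 0)
    d <- sampleDesign("HCT116", doses = c(0, 1), bioReps = 1, techReps = 1,
                      seed = 1)
    tbl <- quantifyBands(generateExperiment(d, effects = eff))
    ss <- secondaryStructureSummary(tbl)
    expect_equal(ss$conversion_pct[ss$dose == 0], 0)
    # overlapping amide I components cross-talk in the second derivative;
    # the noise-free estimate stays inside the 2-point acceptance band
    expect_lt(abs(ss$conversion_pct[ss$dose == 1] - 100 * cv), 2)
    # beta gain must mirror the conserved intensity transfer
    expect_gt(ss$beta_gain_pct[ss$dose == 1], 0)
  }
})

test_that("recovered conversion is strictly increasing in the parameter", {
  conv <- vapply(c(0.1, 0.25, 0.4), function(cv) {
    eff <- effectModel("HCT116", doses = c(0, 1),
                       multipliers = rbind(c(zdna = 1), c(zdna = 1)),
                       conversion = c(0, cv), jitterSD = 0, noiseSD = 0)
    d <- sampleDesign("HCT116", doses = c(0, 1), bioReps = 1, techReps = 1,
                      seed = 1)
    ss <- secondaryStructureSummary(
      quantifyBands(generateExperiment(d, effects = eff)))
    ss$conversion_pct[ss$dose == 1]
  }, numeric(1))
  expect_true(all(diff(conv) > 0))
})

test_that("default band assignments are internally consistent", {
  tbl <- defaultBandAssignments()
  expect_true(all(tbl$center >= tbl$window_low & tbl$center <= tbl$window_high))
  expect_true(all(tbl$source %in% c("absorbance", "second_derivative")))
  expect_false("po2_sym" %in% tbl$band)
  expect_true("po2_sym" %in% defaultBandAssignments(includeDisabled = TRUE)$band)
  # Z-DNA search window is the documented 1071-1061 interval
  z <- tbl[tbl$band == "zdna", ]
  expect_equal(c(z$window_high, z$window_low), c(1071, 1061))
})

test_that("with default noise, parameters are recovered within 3 SEM at n=9", {
  d <- sampleDesign("HCT116", doses = c(0, 1.5), bioReps = 3, techReps = 3,
                    seed = 5)
  tbl <- percentOfUntreated(quantifyBands(generateExperiment(d)))
  z <- zdnaEnhancementRatio(tbl)
  i <- z$dose == 1.5
  # noise-free target for the full default model at 1.5 (Z up, A+B down)
  dq <- sampleDesign("HCT116", doses = c(0, 1.5), bioReps = 1, techReps = 1,
                     seed = 1)
  zq <- zdnaEnhancementRatio(quantifyBands(generateExperiment(
    dq, effects = quietEffect())))
  target <- zq$fold_change[zq$dose == 1.5]
  fold <- z$fold_change[i]
  se <- fold * sqrt((z$ratio_sem[i] / z$ratio_mean[i])^2 +
                    (z$ratio_sem[z$dose == 0] / z$ratio_mean[z$dose == 0])^2)
  expect_lt(abs(fold - target), 3 * se)
})
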