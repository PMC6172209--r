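# preprocessing: reference subtraction, Savitzky-Golay, normalizations,
# region extraction

test_that("subtractReference recovers the mixing coefficient", {
  g <- wavenumberGrid()
  ref <- 0.02 + evaluateBand(list(center = 2125, fwhm = 160, amplitude = 0.05), g)
  # signal flat in the flatten window (bands far from 2200-2050)
  signal <- evaluateBand(list(center = 1650, fwhm = 15, amplitude = 0.6), g) +
    evaluateBand(list(center = 2921, fwhm = 12, amplitude = 0.3), g)
  s <- toySet(matrix(signal + 0.7 * ref, ncol = 1), wn = g)
  out <- subtractReference(s, ref)
  expect_equal(unname(colData(out)$subtraction_k), 0.7, tolerance = 1e-6)
  expect_equal(intensities(out)[, 1], signal, tolerance = 1e-6)
  expect_match(processingLog(out)[2], "background_subtracted")
  # sample == reference: k ~ 1, output ~ 0
  s2 <- toySet(matrix(ref, ncol = 1), wn = g)
  out2 <- subtractReference(s2, ref)
  expect_equal(unname(colData(out2)$subtraction_k), 1, tolerance = 1e-9)
  expect_lt(max(abs(intensities(out2))), 1e-9)
})

test_that("subtractReference rejects degenerate input", {
  g <- wavenumberGrid()
  s <- toySet(matrix(1, length(g), 1), wn = g)
  expect_error(subtractReference(s, rep(0, length(g))), "all zero")
  expect_error(subtractReference(s, rep(1, 100)), "different wavenumber grids")
  # a reference that is a straight line in the window carries no water shape
  expect_error(subtractReference(s, 0.1 + 0.001 * g), "degenerate")
})

test_that("subtractReference is linear in the sample argument", {
  g <- wavenumberGrid()
  ref <- 0.02 + evaluateBand(list(center = 2125, fwhm = 160, amplitude = 0.05), g)
  set.seed(4)
  a <- evaluateBand(list(center = 1500, fwhm = 30, amplitude = 0.4), g) + 0.3 * ref
  b <- evaluateBand(list(center = 1240, fwhm = 12, amplitude = 0.2), g) + 0.9 * ref
  outs <- lapply(list(a, b, a + b), function(v)
    intensities(subtractReference(toySet(matrix(v, ncol = 1), wn = g), ref))[, 1])
  expect_equal(outs[[3]], outs[[1]] + outs[[2]], tolerance = 1e-10)
})

test_that("SG second derivative is exact on quadratics and zero on constants", {
  g <- wavenumberGrid()
  a <- 3e-4
  s <- toySet(cbind(rep(1, length(g)), a * g^2), wn = g)
  d2 <- intensities(savgolDerivative(s, 9, 3, deriv = 2))
  expect_equal(max(abs(d2[, 1])), 0, tolerance = 1e-12)
  expect_equal(d2[, 2], rep(2 * a, length(g)), tolerance = 1e-9)
  # smoothing (deriv = 0) reproduces a cubic exactly, edges included
  s3 <- toySet(matrix(1e-9 * g^3 - g, ncol = 1), wn = g)
  sm <- intensities(savgolDerivative(s3, 9, 3, deriv = 0))
  expect_equal(sm[, 1], 1e-9 * g^3 - g, tolerance = 1e-6)
})

test_that("SG second derivative of a gaussian matches the analytic form", {
  s <- gaussianSet(1066, 10, 0.5)
  d2 <- savgolDerivative(s, 9, 3, deriv = 2)
  v <- intensities(d2)[, 1]
  g <- wavenumbers(s)
  # global minimum at the grid point nearest the band center
  expect_equal(g[which.min(v)], 1066)
  # the 9-point cubic fit attenuates the lobe depth (quartic term of the
  # gaussian over the +/-4 cm-1 window); the estimate must converge to the
  # closed form as the window shrinks
  exact <- gaussD2(g, 1066, 10, 0.5)
  expect_equal(min(v), min(exact), tolerance = 0.25)
  v5 <- intensities(savgolDerivative(s, 5, 3, deriv = 2))[, 1]
  expect_equal(min(v5), min(exact), tolerance = 0.05)
  expect_lt(abs(min(v5) - min(exact)), abs(min(v) - min(exact)))
})

test_that("SG derivative is linear", {
  g <- wavenumberGrid()
  set.seed(11)
  a <- evaluateBand(list(center = 1655, fwhm = 14, amplitude = 0.5), g)
  b <- evaluateBand(list(center = 1240, fwhm = 10, amplitude = 0.2), g)
  d <- function(v) intensities(savgolDerivative(toySet(matrix(v, ncol = 1),
                                                       wn = g), 9, 3, 2))[, 1]
  expect_equal(d(3 * a), 3 * d(a), tolerance = 1e-12)
  expect_equal(d(a + b), d(a) + d(b), tolerance = 1e-12)
})

test_that("SG parameter validation", {
  s <- gaussianSet(1066, 10, 0.5)
  expect_error(savgolDerivative(s, 8, 3, 2), "odd")
  expect_error(savgolDerivative(s, 3, 3, 2), "odd|greater")
  expect_error(savgolDerivative(s, 4001, 3, 2), "longer|odd")
  expect_error(savgolDerivative(s, 9, 1, 2), "deriv")
})

test_that("vector normalization yields unit norm and is idempotent", {
  s <- toySet(matrix(c(3, 4), ncol = 1))
  out <- vectorNormalize(s)
  expect_equal(intensities(out)[, 1], c(0.6, 0.8))
  set.seed(2)
  s2 <- toySet(matrix(rnorm(300), ncol = 3))
  n1 <- vectorNormalize(s2)
  expect_equal(unname(sqrt(colSums(intensities(n1)^2))), rep(1, 3),
               tolerance = 1e-9)
  n2 <- vectorNormalize(n1)
  expect_equal(intensities(n2), intensities(n1), tolerance = 1e-9)
  expect_error(vectorNormalize(toySet(matrix(0, 10, 1))), "zero-norm")
})

test_that("vector normalization over a region scales by the region norm", {
  set.seed(5)
  s <- toySet(matrix(runif(200, 0.1, 1), ncol = 2), wn = seq(199, 100))
  out <- vectorNormalize(s, region = c(150, 180))
  idx <- which(wavenumbers(s) >= 150 & wavenumbers(s) <= 180)
  expect_equal(unname(sqrt(colSums(intensities(out)[idx, ]^2))), rep(1, 2),
               tolerance = 1e-9)
})

test_that("min/max normalization maps [min, anchor max] to [0, 1]", {
  s <- toySet(matrix(c(1, 2, 3), ncol = 1), wn = c(300, 200, 100))
  out <- minmaxNormalize(s, anchorWindow = c(100, 300))
  expect_equal(intensities(out)[, 1], c(0, 0.5, 1))
  expect_error(minmaxNormalize(toySet(matrix(2, 5, 1), wn = 5:1 * 100),
                               anchorWindow = c(100, 500)), "flat")
})

test_that("extractRegion keeps closed-interval grid points in order", {
  s <- toySet(matrix(seq_len(3351), ncol = 1), wn = wavenumberGrid())
  sub <- extractRegion(s, c(1250, 1200))
  expect_equal(nrow(sub), 51)
  expect_equal(wavenumbers(sub)[1], 1250)
  expect_equal(wavenumbers(sub)[51], 1200)
  expect_true(all(diff(wavenumbers(sub)) < 0))
  # full-grid extraction is the identity
  expect_equal(intensities(extractRegion(s, c(4000, 650))), intensities(s))
  expect_error(extractRegion(s, c(5000, 4500)), "does not overlap")
  # nested extraction equals the inner extraction
  inner <- extractRegion(s, c(1240, 1210))
  expect_equal(intensities(extractRegion(sub, c(1240, 1210))),
               intensities(inner))
})

test_that("meanCenter removes the across-sample mean at every wavenumber", {
  set.seed(9)
  s <- toySet(matrix(rnorm(50, 5), ncol = 5))
  out <- meanCenter(s)
  expect_equal(unname(rowMeans(intensities(out))), rep(0, 10),
               tolerance = 1e-12)
})

test_that("processing history is append-only and recorded in order", {
  s <- gaussianSet(1066, 10, 0.5)
  out <- vectorNormalize(savgolDerivative(s, 9, 3, 2))
  expect_equal(processingLog(out),
               c("raw", "second_derivative(w=9,p=3)", "vector_normalized"))
})
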