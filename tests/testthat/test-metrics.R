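mkBoxImage <- function(iw, ib, sdBlack = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(iw, 40, 40)
  m[25:36, 25:36] <- ib + rnorm(144, 0, sdBlack)
  m[m < 0] <- 0
  grayImage(m, 1)
}
toyBoxes <- metricBoxes(c(3, 3, 14, 14), c(25, 25, 36, 36))

test_that("contrast metric reproduces hand-computed values", {
  expect_equal(contrastMetric(mkBoxImage(100, 50), toyBoxes), 0.5)
  expect_equal(contrastMetric(mkBoxImage(80, 80), toyBoxes), 0)
  expect_equal(contrastMetric(mkBoxImage(60, 0), toyBoxes), 1)
  # contrast is scale-invariant but NOT offset-invariant
  img <- mkBoxImage(100, 50)
  shifted <- grayImage(pixels(img) + 10, 1)
  expect_equal(contrastMetric(grayImage(3 * pixels(img), 1), toyBoxes), 0.5)
  expect_false(isTRUE(all.equal(contrastMetric(shifted, toyBoxes), 0.5)))
  zero <- grayImage(matrix(0, 40, 40), 1)
  expect_error(contrastMetric(zero, toyBoxes), "degenerate")
})

test_that("SNR metric is Iw over the black-box sample sd", {
  img <- mkBoxImage(100, 50, sdBlack = 10, seed = 3)
  b <- toyBoxes$blackBox
  sb <- sd(pixels(img)[b[1]:b[3], b[2]:b[4]])
  expect_equal(snrMetric(img, toyBoxes), 100 / sb, tolerance = 1e-12)
  # scale invariance
  expect_equal(snrMetric(grayImage(4 * pixels(img), 1), toyBoxes),
               snrMetric(img, toyBoxes), tolerance = 1e-12)
  # constant black box is degenerate
  expect_error(snrMetric(mkBoxImage(100, 50, sdBlack = 0), toyBoxes),
               "degenerate")
})

test_that("metric boxes are validated", {
  expect_error(metricBoxes(c(1, 1, 5, 5), c(20, 20, 31, 31)), "10 x 10")
  expect_error(metricBoxes(c(1, 1, 12, 12), c(6, 6, 17, 17)), "disjoint")
})

test_that("profile extraction is exact on constants, ramps and steps", {
  cst <- grayImage(matrix(0.3, 32, 32), 1)
  pr <- extractProfile(cst, c(16, 2), c(16, 30))
  expect_equal(unique(pr$intensity), 0.3)

  # bilinear interpolation reproduces a linear ramp exactly
  ramp <- grayImage(matrix(seq_len(32), 32, 32, byrow = TRUE) / 32, 1)
  pr2 <- extractProfile(ramp, c(10, 4), c(10, 28), nSamples = 49)
  fitLine <- lm(intensity ~ position, data = pr2)
  expect_equal(unname(coef(fitLine)[2]), 1 / 32, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fitLine))), 1e-12)

  # a 45-degree line across a vertical step crosses at the known arc length
  stepim <- matrix(0, 64, 64); stepim[, 33:64] <- 1
  pr3 <- extractProfile(grayImage(stepim, 1), c(20, 20), c(44, 44),
                        nSamples = 241)
  mid <- (max(pr3$intensity) + min(pr3$intensity)) / 2
  xCross <- pr3$position[which.min(abs(pr3$intensity - mid))]
  # step edge between columns 32 and 33 lies at col 32.5: 12.5 columns from
  # the start, sqrt(2) arc length per column
  expect_equal(xCross, 12.5 * sqrt(2), tolerance = 0.2)

  expect_error(extractProfile(cst, c(0, 5), c(16, 30)), "inside")
})

test_that("Boltzmann fit recovers exact sigmoid parameters", {
  pr <- boltzmannSamples(0.2, 1.0, x0 = 4.2, dx = 2.0)
  fit <- fitBoltzmann(pr)
  expect_equal(width1090(fit), 2 * 2.0 * log(9), tolerance = 1e-6)
  expect_equal(fit@x0, 4.2, tolerance = 1e-6)
  expect_equal(fit@aLow, 0.2, tolerance = 1e-6)
  expect_equal(fit@aHigh, 1.0, tolerance = 1e-6)
  # the closed-form identity holds for every returned fit (validity slot)
  expect_equal(width1090(fit), 2 * fit@dx * log(9))

  # falling edges are handled by axis reversal
  prFall <- pr; prFall$intensity <- rev(pr$intensity)
  fitF <- fitBoltzmann(prFall)
  expect_equal(width1090(fitF), 2 * 2.0 * log(9), tolerance = 1e-4)
})

test_that("Boltzmann fit of an ideal step is sharp and localized", {
  x <- seq(0, 20, by = 0.1)
  pr <- data.frame(position = x, intensity = ifelse(x < 10.05, 0, 1))
  fit <- fitBoltzmann(pr)
  expect_lt(width1090(fit), 0.5)
  expect_equal(fit@x0, 10.05, tolerance = 0.06)
})

test_that("Boltzmann fit enforces its preconditions", {
  expect_error(fitBoltzmann(data.frame(position = 1:5, intensity = 1:5)),
               "at least 8")
  flat <- data.frame(position = 1:20, intensity = rep(1, 20))
  expect_error(fitBoltzmann(flat), "flat")
  # a profile crossing midrange twice is not edge-like
  x <- seq(-10, 10, by = 0.25)
  bump <- data.frame(position = x, intensity = exp(-x^2 / 4))
  expect_error(fitBoltzmann(bump), "non-edge-like")
})

test_that("blurriness width grows monotonically with blur strength", {
  fx <- defaultPhantomFixture()
  widths <- vapply(c(0.25, 0.5, 1.0), function(lam) {
    psf <- suppressWarnings(lorentzianPSF(lam, spacing = fx$scene$spacing))
    blurrinessMetric(degradeImage(fx$phantom$image, psf, 0),
                     fx$phantom$truth$edge)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  # contrast/width scale invariance: multiplying intensities by c > 0
  bright <- grayImage(3 * pixels(fx$degraded), fx$scene$spacing)
  expect_equal(blurrinessMetric(bright, fx$phantom$truth$edge),
               blurrinessMetric(fx$degraded, fx$phantom$truth$edge),
               tolerance = 1e-6)
})

test_that("report normalization divides by the original arm", {
  mkRep <- function(arm, co, sn, bl)
    new("QualityReport", arm = arm, contrast = co, snr = sn, blurriness = bl,
        normalized = c(contrast = NA_real_, snr = NA_real_,
                       blurriness = NA_real_))
  reps <- normalizeReports(list(mkRep("original", 0.2, 10, 2),
                                mkRep("denoised", 0.2, 4.3, 2.02)))
  expect_equal(unname(reps[[1]]@normalized), c(1, 1, 1))
  expect_equal(unname(reps[[2]]@normalized["snr"]), 0.43)

  single <- normalizeReports(list(mkRep("original", 0.5, 5, 1)))
  expect_equal(unname(single[[1]]@normalized), c(1, 1, 1))

  expect_error(normalizeReports(list(mkRep("other", 1, 1, 1))), "not present")
  expect_error(normalizeReports(list(mkRep("original", 0, 1, 1))),
               "degenerate")
})

test_that("min-max matching aligns profile extrema to the reference", {
  base <- boltzmannSamples(0.1, 0.9, 0, 1.5)
  scaled <- base; scaled$intensity <- 2 * base$intensity + 5
  other <- boltzmannSamples(0.3, 0.5, 1, 2)
  out <- profileMinMaxMatch(list(base, scaled, other))
  expect_equal(out[[1]]$intensity, base$intensity)
  # affine remap recovers the reference exactly
  expect_equal(out[[2]]$intensity, base$intensity, tolerance = 1e-12)
  for (pr in out) {
    expect_equal(min(pr$intensity), min(base$intensity))
    expect_equal(max(pr$intensity), max(base$intensity))
  }
  flat <- data.frame(position = 1:10, intensity = rep(2, 10))
  expect_error(profileMinMaxMatch(list(flat)), "degenerate")
})
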