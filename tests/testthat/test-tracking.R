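test_that("manual origin is the mean of three points, order-free", {
  expect_equal(manualOrigin(rbind(c(0, 0), c(0, 0), c(0, 0))), c(0, 0))
  expect_equal(manualOrigin(rbind(c(0, 0), c(3, 0), c(0, 3))), c(1, 1))
  pts <- rbind(c(2.5, 1), c(4, 7), c(9, 3.5))
  expect_equal(manualOrigin(pts), manualOrigin(pts[c(3, 1, 2), ]))
  expect_error(manualOrigin(rbind(c(0, 0), c(1, 1))), "three")
})

test_that("mask rasterization follows pixel-center point-in-polygon", {
  frame <- grayImage(matrix(runif(40 * 40), 40, 40), 1)
  # axis-aligned rectangle with vertices on pixel boundaries: w x h pixels
  rect <- rbind(c(10.5, 10.5), c(10.5, 20.5), c(20.5, 20.5), c(20.5, 10.5))
  mask <- buildMask(frame, rect)
  expect_equal(sum(mask@mask), 10L * 10L)
  expect_equal(mask@centroid, c(15.5, 15.5))
  expect_length(mask@referencePatch, 100L)

  # triangle over half a 10 x 10 square: about 50 px
  tri <- rbind(c(10.5, 10.5), c(10.5, 20.5), c(20.5, 10.5))
  triMask <- buildMask(frame, tri)
  expect_lte(abs(sum(triMask@mask) - 50), 5)

  # independent even-odd oracle (mgcv::in.out) agrees pixel by pixel
  skipIfNot <- requireNamespace("mgcv", quietly = TRUE)
  if (skipIfNot) {
    poly <- rbind(c(12.2, 11.7), c(13.1, 25.4), c(24.8, 27.2),
                  c(27.5, 14.1), c(18.0, 9.6))
    m <- buildMask(frame, poly)
    grid <- which(matrix(TRUE, 40, 40), arr.ind = TRUE)
    oracle <- mgcv::in.out(rbind(poly, poly[1, ]),
                           cbind(as.numeric(grid[, 1]),
                                 as.numeric(grid[, 2])))
    expect_equal(as.vector(m@mask), as.vector(oracle))
  }

  # degenerate collinear polygon rasterizes empty
  expect_error(buildMask(frame, rbind(c(5, 5), c(5, 15), c(5, 25))), "empty")
  expect_error(buildMask(frame, rbind(c(0, 5), c(5, 15), c(15, 25))),
               "inside")
})

test_that("MSSD score matches brute-force hand computation", {
  ref <- grayImage(matrix(c(1, 3, 2, 4), 2, 2), 1)  # [1 2; 3 4] row-wise
  obj <- grayImage(matrix(c(2, 3, 2, 4), 2, 2), 1)  # [2 2; 3 4]
  # full 2x2 mask via a rectangle covering all pixel centers
  mask <- buildMask(ref, rbind(c(0.5, 0.5), c(0.5, 2.5), c(2.5, 2.5),
                               c(2.5, 0.5)))
  expect_equal(mssdScore(mask, ref, c(0L, 0L)), 0)
  expect_equal(mssdScore(mask, obj, c(0L, 0L)), (1^2 + 0 + 0 + 0) / 4)
  # constant shift under the mask gives c^2
  shifted <- grayImage(pixels(ref) + 3, 1)
  expect_equal(mssdScore(mask, shifted, c(0L, 0L)), 9)
  expect_error(mssdScore(mask, obj, c(5L, 0L)), "outside")
})

test_that("tracker recovers every integer in-window shift exactly", {
  cfg <- smallCineConfig(trajectory = rbind(c(0L, 0L)))
  cine <- makeCineSequence(cfg)
  refFrame <- cine$frames[[1]]
  roi <- circleROI(cine$truth$start, cine$truth$radiusPx + 2)
  mask <- buildMask(refFrame, roi)
  p <- pixels(refFrame)
  for (dr in -5:5) for (dc in -5:5) {
    shiftedFrame <- grayImage(
      p[pmin(pmax(seq_len(nrow(p)) - dr, 1), nrow(p)),
        pmin(pmax(seq_len(ncol(p)) - dc, 1), ncol(p))], 0.784)
    r <- locateTumor(mask, shiftedFrame)
    expect_true(isDetected(r))
    expect_equal(trackedPosition(r) - mask@centroid, c(dr, dc))
  }
})

test_that("uniform frames and two-copy scenes are undetected", {
  set.seed(21)
  frame <- grayImage(matrix(runif(96 * 96, 0.4, 0.6), 96, 96), 0.784)
  roi <- circleROI(c(48, 48), 10)
  mask <- buildMask(frame, roi)
  r <- locateTumor(mask, grayImage(matrix(0.5, 96, 96), 0.784))
  expect_false(isDetected(r))
  expect_equal(length(unique(as.vector(scoreSurface(r)))), 1L)

  # two identical copies of the masked pattern at two in-window offsets
  ref <- matrix(0, 64, 64)
  patch <- matrix(c(5, 1, 2, 7, 3, 9, 4, 8, 6), 3, 3)
  ref[31:33, 31:33] <- patch
  refIm <- grayImage(ref, 1)
  m2 <- buildMask(refIm, rbind(c(30.5, 30.5), c(30.5, 33.5),
                               c(33.5, 33.5), c(33.5, 30.5)))
  obj <- matrix(0, 64, 64)
  obj[31:33, 28:30] <- patch  # offset (0, -3)
  obj[31:33, 34:36] <- patch  # offset (0, +3)
  r2 <- locateTumor(m2, grayImage(obj, 1))
  expect_false(isDetected(r2))
  expect_equal(min(scoreSurface(r2)), 0)
})

test_that("affine intensity maps leave the MSSD argmin unchanged", {
  cfg <- smallCineConfig(trajectory = defaultTrajectory(6, 3, 2, 5),
                         noiseSD = 0.005)
  cine <- makeCineSequence(cfg)
  roi <- circleROI(cine$truth$start, cine$truth$radiusPx + 2)
  gain <- 3.7; offset <- 0.9
  maskA <- buildMask(cine$frames[[1]], roi)
  mapped <- lapply(cine$frames, function(f)
    grayImage(gain * pixels(f) + offset, pixelSpacing(f)))
  maskB <- buildMask(mapped[[1]], roi)
  for (k in 2:6) {
    ra <- locateTumor(maskA, cine$frames[[k]])
    rb <- locateTumor(maskB, mapped[[k]])
    expect_equal(trackedPosition(ra), trackedPosition(rb))
    # scores scale by the square of the gain
    expect_equal(scoreSurface(rb), gain^2 * scoreSurface(ra),
                 tolerance = 1e-9)
  }
})

test_that("accuracy evaluation fills d and e with the mm conversion", {
  mkRes <- function(k, tracked, manual, detected = TRUE)
    new("FrameTrackResult", frame = as.integer(k), tracked = tracked,
        manual = manual, d = c(NA_real_, NA_real_),
        e = c(NA_real_, NA_real_), surface = matrix(0, 1, 1),
        detected = detected)
  spacing <- 0.784
  res <- list(mkRes(1, c(50, 50), c(50.4, 50.1)),
              mkRes(2, c(53, 48), c(53.4, 48.1)),
              mkRes(3, c(51, 52), c(53.4, 52.1)))
  out <- evaluateAccuracy(res, spacing)
  expect_equal(out[[1]]@e, c(0, 0))
  expect_equal(out[[2]]@e, c(0, 0), tolerance = 1e-12)  # perfect tracking
  # frame 3 tracked 2 px short in rows: e = +2 px * spacing in SI
  expect_equal(out[[3]]@e, c(2 * spacing, 0), tolerance = 1e-12)

  # a constant +2 px row bias in tracking gives e row = -2 * spacing
  resB <- list(mkRes(1, c(50, 50), c(50, 50)),
               mkRes(2, c(55, 50), c(53, 50)),
               mkRes(3, c(52, 50), c(50, 50)))
  outB <- evaluateAccuracy(resB, spacing)
  for (k in 2:3) expect_equal(outB[[k]]@e, c(-2 * spacing, 0))

  # undetected reference is unrecoverable
  resC <- res; resC[[1]]@detected <- FALSE
  expect_error(evaluateAccuracy(resC, spacing), "reference")
})

test_that("error summaries use absolute per-axis components", {
  mkRes <- function(k, e, detected = TRUE)
    new("FrameTrackResult", frame = as.integer(k),
        tracked = c(0, 0), manual = c(0, 0), d = c(0, 0), e = e,
        surface = matrix(0, 1, 1), detected = detected)
  res <- list(mkRes(1, c(0, 0)),
              mkRes(2, c(1, -1)), mkRes(3, c(-2, 2)), mkRes(4, c(3, -3)))
  s <- summarizeErrors(res)
  expect_equal(s$meanSI, 2); expect_equal(s$sdSI, 1)
  expect_equal(s$meanLR, 2); expect_equal(s$sdLR, 1)
  expect_equal(s$nDetected + s$nUndetected, s$nFrames)

  resU <- list(mkRes(1, c(0, 0)), mkRes(2, c(1, 1), detected = FALSE))
  expect_error(summarizeErrors(resU), "no detected")
})

test_that("noisy tracking stays within 1 px on nearly all frames", {
  # noise sd at 10% of the blob contrast, 200 object frames
  contrastAbs <- abs(-0.2 * 0.5)
  cfg <- smallCineConfig(trajectory = defaultTrajectory(201, 4, 2, 13),
                         noiseSD = 0.1 * contrastAbs, seed = 42L)
  cine <- makeCineSequence(cfg)
  roi <- circleROI(cine$truth$start, cine$truth$radiusPx + 2)
  mask <- buildMask(cine$frames[[1]], roi)
  res <- trackSequence(mask, cine$frames, cine$truth$centers)
  errs <- vapply(seq_along(res), function(k) {
    if (!isDetected(res[[k]])) return(Inf)
    max(abs(trackedPosition(res[[k]]) - mask@centroid -
              (cine$truth$centers[k, ] - cine$truth$centers[1, ])))
  }, numeric(1))
  expect_gte(mean(errs[-1] <= 1), 0.95)
})
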