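# Shared fixtures, all generated in code.

# Standard-resolution phantom scene at the default study conditions.
defaultPhantomFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sceneConfig()
      ph <- makeQC3Phantom(sc)
      psf <- suppressWarnings(lorentzianPSF(sc$psfLambda,
                                            sc$psfSupportHalfWidth,
                                            sc$spacing))
      deg <- degradeImage(ph$image, psf, sc$noiseSD, seed = sc$seed)
      cache <<- list(scene = sc, phantom = ph, psf = psf, degraded = deg,
                     boxes = metricBoxes(ph$truth$whiteBox,
                                         ph$truth$blackBox))
    }
    cache
  }
})

# Small cine scene for tracker tests.
smallCineConfig <- function(trajectory = defaultTrajectory(11, 3, 2, 7),
                            noiseSD = 0, seed = 7L, ...) {
  sceneConfig(imageShape = c(96L, 96L), noiseSD = noiseSD,
              trajectory = trajectory, tumorRadiusPx = 9, seed = seed, ...)
}

circleROI <- function(center, radius, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  cbind(center[1] + radius * sin(th), center[2] + radius * cos(th))
}

# Exact Boltzmann samples for fit-recovery tests.
boltzmannSamples <- function(aLow, aHigh, x0, dx,
                             x = seq(x0 - 12 * dx, x0 + 12 * dx,
                                     length.out = 101)) {
  data.frame(position = x,
             intensity = aLow + (aHigh - aLow) * stats::plogis((x - x0) / dx))
}
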