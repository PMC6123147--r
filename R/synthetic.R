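## Synthetic scene generation: the forward model g = Hf + eta with known
## ground truth, a bar-pattern quality phantom, and moving-tumor cine
## sequences emulating low-contrast megavoltage portal imaging.

#' Discretize a Lorentzian point spread function
#'
#' Samples the normalized Lorentzian 1 / (1 + (x^2 + y^2)/lambda^2)^{3/2}
#' at pixel centers on a square support and renormalizes the result to unit
#' sum. The continuous form has heavy tails (the mass outside radius R is
#' lambda / sqrt(lambda^2 + R^2)), so compact supports necessarily truncate
#' a noticeable fraction of the mass; a warning reports the truncated
#' fraction when it exceeds 1\%.
#'
#' @param lambda Lorentzian width parameter, mm (> 0). 0.5 is a
#'   representative value for a 6 MV beam on an amorphous-silicon imager.
#' @param supportHalfWidth integer half-width of the kernel support in
#'   pixels (>= 1); the kernel is (2 hw + 1) square.
#' @param spacing pixel spacing in mm.
#' @return A \linkS4class{PSFModel}.
#' @examples
#' psf <- suppressWarnings(lorentzianPSF(0.5, spacing = 0.784))
#' sum(psfKernel(psf))  # 1
#' @export
lorentzianPSF <- function(lambda,
                          supportHalfWidth = ceiling(6 * lambda / spacing),
                          spacing = 1) {
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be a positive number (mm)")
  hw <- as.integer(supportHalfWidth)
  if (!is.finite(hw) || hw < 1L)
    stop("supportHalfWidth must be a positive integer")
  if (!is.finite(spacing) || spacing <= 0)
    stop("spacing must be positive (mm)")
  xs <- (-hw:hw) * spacing
  r2 <- outer(xs^2, xs^2, "+")
  k <- 1 / (1 + r2 / lambda^2)^1.5
  ## mass outside the inscribed disc of the support, relative to the full
  ## continuous mass 2*pi*lambda^2 (closed form for the Lorentzian^{3/2})
  truncFrac <- lambda / sqrt(lambda^2 + (hw * spacing)^2)
  if (truncFrac >= 0.01)
    warning(sprintf(
      "kernel support truncates >= %.1f%% of the continuous PSF mass; tails are renormalized into the support",
      100 * truncFrac))
  k <- k / sum(k)
  new("PSFModel", lambda = lambda, kernel = k, supportHalfWidth = hw,
      spacing = as.numeric(spacing))
}

#' Identity point spread function
#'
#' A single-entry kernel, useful as a no-blur control (H = I).
#'
#' @param spacing pixel spacing in mm.
#' @return A \linkS4class{PSFModel} whose kernel is the 1x1 matrix 1.
#' @export
identityPSF <- function(spacing = 1) {
  new("PSFModel", lambda = 1e-6, kernel = matrix(1, 1, 1),
      supportHalfWidth = 0L, spacing = as.numeric(spacing))
}

## Mirror ("symmetric", edge-inclusive) padding of a matrix by hw pixels.
mirrorPad <- function(x, hw) {
  if (hw == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  if (hw > n || hw > m) stop("padding exceeds image size")
  ri <- c(hw:1, 1:n, n:(n - hw + 1))
  ci <- c(hw:1, 1:m, m:(m - hw + 1))
  x[ri, ci]
}

## 2D linear convolution with mirror boundary handling, via FFT on a
## mirror-padded grid (padded further to a highly composite size).
convolve2Mirror <- function(x, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  hw <- max(kh, kw)
  if (nrow(kernel) > nrow(x) || ncol(kernel) > ncol(x))
    stop("kernel larger than image")
  if (hw == 0L) return(x * kernel[1, 1])
  p <- mirrorPad(x, hw)
  N <- nextn(nrow(p)); M <- nextn(ncol(p))
  P <- matrix(0, N, M)
  P[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  K <- matrix(0, N, M)
  ri <- ((-kh:kh) %% N) + 1L
  ci <- ((-kw:kw) %% M) + 1L
  K[ri, ci] <- kernel
  out <- Re(fft(fft(P) * fft(K), inverse = TRUE)) / (N * M)
  out[hw + seq_len(nrow(x)), hw + seq_len(ncol(x))]
}

#' Apply the forward degradation model g = Hf + eta
#'
#' Convolves the ideal image with the PSF kernel (symmetric/mirror boundary
#' padding, so constant images stay constant up to the borders) and adds
#' zero-mean Gaussian noise. Negative results are clipped to zero. The
#' result is bit-reproducible for a fixed seed.
#'
#' @param ideal a \linkS4class{GrayImage}, the pristine image f.
#' @param psf a \linkS4class{PSFModel}, the blur operator H.
#' @param noiseSD standard deviation of the additive Gaussian noise, in
#'   intensity units (>= 0).
#' @param seed integer seed for the noise field.
#' @return A degraded \linkS4class{GrayImage} g.
#' @export
degradeImage <- function(ideal, psf, noiseSD = 0, seed = 1L) {
  stopifnot(is(ideal, "GrayImage"), is(psf, "PSFModel"))
  if (!is.finite(noiseSD) || noiseSD < 0) stop("noiseSD must be >= 0")
  g <- convolve2Mirror(pixels(ideal), psfKernel(psf))
  if (noiseSD > 0) {
    eta <- withr::with_seed(as.integer(seed),
      matrix(stats::rnorm(length(g), 0, noiseSD), nrow(g), ncol(g)))
    g <- g + eta
  }
  g[g < 0] <- 0
  grayImage(g, pixelSpacing(ideal))
}

#' Scene configuration for the synthetic generators
#'
#' Bundles and validates the parameters of both synthetic scenes. Defaults
#' describe a 512 x 384 px portal image at 0.784 mm spacing with a weak
#' (8\%) contrast between reference regions, a Lorentzian blur of
#' lambda = 0.5 mm, and mild additive noise -- the low-contrast, blurred,
#' noisy regime of megavoltage portal imaging.
#'
#' @param imageShape integer (rows, cols) of each frame.
#' @param spacing pixel spacing, mm.
#' @param backgroundLevel mean background intensity (arbitrary linear
#'   units; defaults keep the scene within [0, 1]).
#' @param tumorContrast fractional intensity increment (positive) or
#'   decrement (negative) of the tumor blob relative to backgroundLevel.
#' @param tumorRadiusPx tumor blob radius in pixels (> 1).
#' @param trajectory integer matrix (n frames x 2) of per-frame (row, col)
#'   offsets of the tumor center from its start position.
#' @param noiseSD additive Gaussian noise sd, intensity units (>= 0).
#' @param psfLambda Lorentzian blur parameter, mm (> 0).
#' @param psfSupportHalfWidth kernel support half-width, px.
#' @param quantStep intensity quantization step applied after degradation
#'   (0 disables). Emulates the discrete pixel levels of detector readout;
#'   exact ties in matching scores only arise on quantized data.
#' @param seed integer master seed for the scene.
#' @param contrastFraction fractional deviation of the phantom's white and
#'   black reference levels from backgroundLevel (phantom scenes).
#' @param searchHalfWidth tracker search-window half-width the trajectory
#'   must respect, px.
#' @return A validated list of class "sceneConfig".
#' @export
sceneConfig <- function(imageShape = c(384L, 512L),
                        spacing = 0.784,
                        backgroundLevel = 0.5,
                        tumorContrast = -0.2,
                        tumorRadiusPx = 12,
                        trajectory = defaultTrajectory(),
                        noiseSD = 0.01,
                        psfLambda = 0.5,
                        psfSupportHalfWidth = ceiling(6 * psfLambda / spacing),
                        quantStep = 0,
                        seed = 1L,
                        contrastFraction = 0.02,
                        searchHalfWidth = 5L) {
  imageShape <- as.integer(imageShape)
  if (length(imageShape) != 2L || any(imageShape < 16L))
    stop("imageShape must be two integers >= 16")
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  if (tumorRadiusPx <= 1) stop("tumorRadiusPx must exceed 1")
  if (psfLambda <= 0) stop("psfLambda must be positive")
  trajectory <- matrix(as.integer(trajectory), ncol = 2)
  if (nrow(trajectory) < 1L) stop("trajectory must be non-empty")
  if (any(abs(trajectory) > searchHalfWidth))
    stop("every trajectory offset must lie within the search window half-width")
  structure(list(
    imageShape = imageShape, spacing = spacing,
    backgroundLevel = backgroundLevel, tumorContrast = tumorContrast,
    tumorRadiusPx = tumorRadiusPx, trajectory = trajectory,
    noiseSD = noiseSD, psfLambda = psfLambda,
    psfSupportHalfWidth = as.integer(psfSupportHalfWidth),
    quantStep = quantStep, seed = as.integer(seed),
    contrastFraction = contrastFraction,
    searchHalfWidth = as.integer(searchHalfWidth)), class = "sceneConfig")
}

#' Default breathing-like tumor trajectory
#'
#' A quasi-periodic superior--inferior dominated excursion within +/- 4 px,
#' safely inside the default 10 x 10 px search window. One reference frame
#' plus 75 object frames.
#'
#' @param nFrames total number of frames including the reference.
#' @param amplitudeRow,amplitudeCol peak offsets (px) along rows
#'   (superior--inferior) and columns (left--right).
#' @param period breathing period in frames.
#' @return Integer matrix (nFrames x 2) of (row, col) offsets; row 1 is 0,0.
#' @export
defaultTrajectory <- function(nFrames = 76L, amplitudeRow = 4,
                              amplitudeCol = 2, period = 12) {
  k <- seq_len(nFrames) - 1L
  cbind(round(amplitudeRow * sin(2 * pi * k / period)),
        round(amplitudeCol * sin(2 * pi * k / period + pi / 3)))
}

#' Generate a bar-pattern quality phantom with annotations
#'
#' Builds a pristine (pre-degradation) phantom inspired by bar-pattern
#' quality-control phantoms: five vertical-bar groups at distinct spatial
#' frequencies, a white and a black reference square, and a large
#' two-level region split by a tilted edge for blurriness measurement.
#' All metric regions are returned as annotations so that metrics never
#' depend on hard-coded coordinates.
#'
#' @param config a \link{sceneConfig}.
#' @return A list with elements \code{image} (\linkS4class{GrayImage}) and
#'   \code{truth}: \code{whiteBox}, \code{blackBox} (1-based inclusive
#'   (row0, col0, row1, col1)), \code{edge} (list p0, p1 endpoints of the
#'   profile line crossing the tilted edge), \code{barGroups} (list of
#'   per-group geometry: rows, cols, barWidth, nBars), \code{levels}
#'   (white, black, background).
#' @export
makeQC3Phantom <- function(config = sceneConfig()) {
  nr <- config$imageShape[1]; nc <- config$imageShape[2]
  if (nr < 128L || nc < 128L)
    stop("imageShape too small for the phantom layout (needs >= 128 x 128)")
  bg <- config$backgroundLevel
  white <- bg * (1 + config$contrastFraction)
  black <- bg * (1 - config$contrastFraction)
  open <- 2 * bg  # unattenuated open-field surround (brightest region)

  ## bright open-field surround with the attenuating plate inset from the
  ## field edge; the plate occupies the bottom of the intensity range, as
  ## in a real megavoltage portal image of an attenuating phantom
  img <- matrix(open, nr, nc)
  plateR <- seq.int(round(nr * 0.05), round(nr * 0.95))
  plateC <- seq.int(round(nc * 0.04), round(nc * 0.96))
  img[plateR, plateC] <- bg

  ## --- tilted-edge region: left half white, right half black, separated by
  ## a near-vertical edge tilted ~5 degrees, occupying the upper plate block
  er <- seq.int(round(nr * 0.10), round(nr * 0.42))
  ec <- seq.int(round(nc * 0.06), round(nc * 0.45))
  tilt <- tan(5 * pi / 180)
  cEdgeMid <- (min(ec) + max(ec)) / 2
  rEdgeMid <- (min(er) + max(er)) / 2
  for (r in er) {
    cEdge <- cEdgeMid + tilt * (r - rEdgeMid)
    img[r, ec] <- ifelse(ec + 0.0 < cEdge, white, black)
  }
  edge <- list(p0 = c(rEdgeMid, cEdgeMid - 20), p1 = c(rEdgeMid, cEdgeMid + 20))

  ## --- reference squares: 14x14, adjacent across the tilted edge (the
  ## blurriness profile runs from one into the other)
  boxHalf <- 7L
  wc <- round(cEdgeMid - 18)
  bc <- round(cEdgeMid + 18)
  br <- round(rEdgeMid)
  whiteBox <- c(br - boxHalf, wc - boxHalf, br + boxHalf - 1L, wc + boxHalf - 1L)
  blackBox <- c(br - boxHalf, bc - boxHalf, br + boxHalf - 1L, bc + boxHalf - 1L)

  ## --- five bar groups (alternating white/black vertical bars), widths in
  ## descending order -> increasing spatial frequency
  barWidths <- c(8L, 6L, 4L, 3L, 2L)
  nBars <- 5L  # white bars per group; black gaps of equal width between
  groupRows <- seq.int(round(nr * 0.55), round(nr * 0.9))
  barGroups <- vector("list", length(barWidths))
  c0 <- round(nc * 0.06)
  for (i in seq_along(barWidths)) {
    w <- barWidths[i]
    groupWidth <- (2L * nBars - 1L) * w
    cols <- seq.int(c0, c0 + groupWidth - 1L)
    if (max(cols) > nc - 4L) stop("imageShape too small for the bar groups")
    block <- matrix(black, length(groupRows), groupWidth)
    for (b in seq_len(nBars)) {
      bc0 <- (b - 1L) * 2L * w + 1L
      block[, bc0:(bc0 + w - 1L)] <- white
    }
    img[groupRows, cols] <- block
    barGroups[[i]] <- list(rows = range(groupRows), cols = range(cols),
                           barWidth = w, nBars = nBars)
    c0 <- c0 + groupWidth + max(12L, 2L * w)
  }

  list(image = grayImage(img, config$spacing),
       truth = list(whiteBox = whiteBox, blackBox = blackBox, edge = edge,
                    barGroups = barGroups,
                    levels = list(white = white, black = black,
                                  background = bg)))
}

## Smooth-edged elliptical blob amplitude field (raised-cosine taper).
blobField <- function(nr, nc, center, radius, axisRatio = 0.85, angle = 0.3) {
  r <- matrix(seq_len(nr), nr, nc) - center[1]
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  u <- cos(angle) * r + sin(angle) * c
  v <- -sin(angle) * r + cos(angle) * c
  rho <- sqrt((u / radius)^2 + (v / (radius * axisRatio))^2)
  a <- 0.5 * (1 + cos(pi * pmin(rho, 1)))
  a
}

#' Generate a moving-tumor cine sequence with ground truth
#'
#' Each frame contains a smooth-edged elliptical blob (the tumor) at the
#' configured trajectory offset over a fixed structured background (a
#' low-frequency illumination gradient plus rib-like horizontal bands).
#' Every frame is degraded independently through \link{degradeImage} with a
#' per-frame seed derived from the scene seed; optional quantization
#' emulates discrete detector levels. Ground truth records the exact blob
#' center of every frame.
#'
#' @param config a \link{sceneConfig}.
#' @return A list with \code{frames} (list of \linkS4class{GrayImage}),
#'   \code{truth} (list: \code{centers} n x 2 matrix of true (row, col)
#'   centers, \code{start}, \code{radiusPx}), and \code{psf}
#'   (the \linkS4class{PSFModel} used).
#' @export
makeCineSequence <- function(config = sceneConfig()) {
  nr <- config$imageShape[1]; nc <- config$imageShape[2]
  traj <- config$trajectory
  nF <- nrow(traj)
  start <- c(round(nr / 2), round(nc / 2))
  centers <- sweep(traj, 2, start, "+")
  rad <- config$tumorRadiusPx
  margin <- ceiling(rad) + config$searchHalfWidth + 2L
  if (any(centers[, 1] < margin) || any(centers[, 1] > nr - margin) ||
      any(centers[, 2] < margin) || any(centers[, 2] > nc - margin))
    stop("tumor blob exits frame bounds along the trajectory")

  bg <- config$backgroundLevel
  rr <- matrix(seq_len(nr) / nr, nr, nc)
  cc <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  background <- bg * (1 + 0.10 * (cc - 0.5) + 0.06 * (rr - 0.5) +
                        0.04 * sin(2 * pi * rr * nr / 48))
  psf <- suppressWarnings(lorentzianPSF(config$psfLambda,
                                        config$psfSupportHalfWidth,
                                        config$spacing))
  amp <- config$tumorContrast * bg
  frames <- vector("list", nF)
  for (k in seq_len(nF)) {
    ideal <- background + amp * blobField(nr, nc, centers[k, ], rad)
    ideal[ideal < 0] <- 0
    fr <- degradeImage(grayImage(ideal, config$spacing), psf,
                       config$noiseSD, seed = config$seed + 1000L * k)
    if (config$quantStep > 0) {
      q <- round(pixels(fr) / config$quantStep) * config$quantStep
      fr <- grayImage(q, config$spacing)
    }
    frames[[k]] <- fr
  }
  list(frames = frames,
       truth = list(centers = centers, start = start, radiusPx = rad),
       psf = psf)
}
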