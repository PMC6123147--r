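## Portal image quality metrics: contrast (Iw - Ib)/Iw, SNR Iw/sigma_b,
## and blurriness as the 10-90% width of a Boltzmann sigmoid fitted to a
## tilted-edge profile; plus normalization to the original arm and
## min-max-matched profile comparison.

#' Metric box pair for contrast and SNR
#'
#' Rectangles (1-based, inclusive (row0, col0, row1, col1)) inside the
#' white and black reference regions. Iw and Ib are mean intensities over
#' the white and black boxes; sigma_b is the sample standard deviation
#' over the black box.
#'
#' @param whiteBox,blackBox integer vectors (row0, col0, row1, col1).
#' @return A validated list of class "metricBoxes".
#' @export
metricBoxes <- function(whiteBox, blackBox) {
  chk <- function(b, nm) {
    b <- as.integer(round(b))
    if (length(b) != 4L) stop(nm, " must be (row0, col0, row1, col1)")
    if (b[3] - b[1] + 1L < 10L || b[4] - b[2] + 1L < 10L)
      stop(nm, " must be at least 10 x 10 px")
    b
  }
  w <- chk(whiteBox, "whiteBox"); b <- chk(blackBox, "blackBox")
  overlap <- w[1] <= b[3] && b[1] <= w[3] && w[2] <= b[4] && b[2] <= w[4]
  if (overlap) stop("whiteBox and blackBox must be disjoint")
  structure(list(whiteBox = w, blackBox = b), class = "metricBoxes")
}

boxPixels <- function(image, box) {
  p <- pixels(image)
  if (box[1] < 1L || box[2] < 1L || box[3] > nrow(p) || box[4] > ncol(p))
    stop("metric box outside image bounds")
  p[box[1]:box[3], box[2]:box[4]]
}

#' Contrast metric (Iw - Ib) / Iw
#'
#' @param image a \linkS4class{GrayImage}.
#' @param boxes a \link{metricBoxes}.
#' @return The contrast value; 0 for equal region means, 1 when the black
#'   region mean is 0.
#' @export
contrastMetric <- function(image, boxes) {
  iw <- mean(boxPixels(image, boxes$whiteBox))
  ib <- mean(boxPixels(image, boxes$blackBox))
  if (iw <= 0) stop("degenerate region: white-box mean must be positive")
  (iw - ib) / iw
}

#' Signal-to-noise ratio Iw / sigma_b
#'
#' Mean intensity of the white box over the sample (n - 1) standard
#' deviation of the black box.
#'
#' @inheritParams contrastMetric
#' @return The SNR value; invariant under multiplication of all
#'   intensities by a positive constant.
#' @export
snrMetric <- function(image, boxes) {
  iw <- mean(boxPixels(image, boxes$whiteBox))
  sb <- stats::sd(as.vector(boxPixels(image, boxes$blackBox)))
  if (sb <= 0) stop("degenerate region: black box is constant (sd = 0)")
  iw / sb
}

#' Sample an intensity profile along a line
#'
#' Bilinear interpolation at evenly spaced points between two endpoints.
#' Positions are arc length along the line in pixel units (oblique lines
#' therefore have non-integer sample positions).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param p0,p1 numeric (row, col) endpoints, inside the image.
#' @param nSamples number of samples; the default oversamples the line's
#'   pixel length 4-fold.
#' @return A data.frame with columns \code{position} (px along the line)
#'   and \code{intensity}.
#' @export
extractProfile <- function(image, p0, p1,
                           nSamples = max(8L, 4L * ceiling(sqrt(sum((p1 - p0)^2))))) {
  p <- pixels(image)
  nr <- nrow(p); nc <- ncol(p)
  for (pt in list(p0, p1))
    if (pt[1] < 1 || pt[1] > nr || pt[2] < 1 || pt[2] > nc)
      stop("profile endpoints must lie inside the image")
  t <- seq(0, 1, length.out = nSamples)
  rows <- p0[1] + t * (p1[1] - p0[1])
  cols <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(pmax(floor(rows), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(cols), 1L), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  val <- (1 - fr) * (1 - fc) * p[cbind(r0, c0)] +
         (1 - fr) * fc       * p[cbind(r0, c0 + 1L)] +
         fr       * (1 - fc) * p[cbind(r0 + 1L, c0)] +
         fr       * fc       * p[cbind(r0 + 1L, c0 + 1L)]
  data.frame(position = t * sqrt(sum((p1 - p0)^2)), intensity = val)
}

## Count crossings of a lightly smoothed profile through its midrange,
## with a 40-60% hysteresis band so noise riding on the edge does not
## register as extra crossings; edge-like profiles cross exactly once.
midrangeCrossings <- function(y) {
  k <- max(3L, 2L * (length(y) %/% 40L) + 1L)
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys <- ys[!is.na(ys)]
  lo <- min(ys); hi <- max(ys)
  s <- ifelse(ys > lo + 0.6 * (hi - lo), 1L,
              ifelse(ys < lo + 0.4 * (hi - lo), -1L, 0L))
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Fit a Boltzmann sigmoid to an edge profile
#'
#' Nonlinear least squares fit of
#' y = aLow + (aHigh - aLow) / (1 + exp(-(x - x0)/dx)) to a sampled edge
#' profile, by Levenberg--Marquardt with data-driven initialization
#' (asymptotes from the 5th/95th percentiles, x0 from the midrange
#' crossing, dx from the finite-difference slope there) and up to 5
#' deterministic restarts with rescaled initial dx. Falling edges are fit
#' on the reversed axis. The blurriness measure is the 10--90\% width,
#' 2 * dx * log(9).
#'
#' @param profile data.frame with columns \code{position} and
#'   \code{intensity} (as from \link{extractProfile}), >= 8 samples
#'   spanning both asymptotes and crossing the midrange once.
#' @return A \linkS4class{BoltzmannFit}.
#' @export
fitBoltzmann <- function(profile) {
  x <- profile$position; y <- profile$intensity
  if (length(x) < 8L) stop("profile must contain at least 8 samples")
  if (max(y) - min(y) <= 0) stop("flat profile: no edge to fit")
  nCross <- midrangeCrossings(y)
  if (nCross != 1L)
    stop(sprintf("non-edge-like profile: %d midrange crossings (need exactly 1)", nCross))

  rising <- stats::cor(x, y) >= 0
  xs <- if (rising) x else -x

  aLow0 <- stats::quantile(y, 0.05, names = FALSE)
  aHigh0 <- stats::quantile(y, 0.95, names = FALSE)
  mid <- (aLow0 + aHigh0) / 2
  ord <- order(xs)
  yo <- y[ord]; xo <- xs[ord]
  iCross <- which(diff(sign(yo - mid)) != 0)[1]
  if (is.na(iCross)) iCross <- which.min(abs(yo - mid))
  x00 <- xo[iCross]
  slope <- (yo[min(iCross + 1L, length(yo))] - yo[max(iCross - 1L, 1L)]) /
    max(xo[min(iCross + 1L, length(xo))] - xo[max(iCross - 1L, 1L)],
        .Machine$double.eps)
  dx0 <- (aHigh0 - aLow0) / (4 * max(abs(slope), .Machine$double.eps))
  dx0 <- min(max(dx0, 1e-3), diff(range(xs)))

  resid <- function(par)
    y - (par[1] + (par[2] - par[1]) * stats::plogis((xs - par[3]) / par[4]))
  ## slopes steeper than the sample spacing are not resolvable: bound dx
  ## at a fifth of the median spacing rather than letting it collapse
  dxMin <- max(1e-6, 0.2 * stats::median(diff(sort(xs))))
  dx0 <- max(dx0, dxMin)
  best <- NULL
  for (scaleF in c(1, 0.5, 2, 0.1, 5)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(aLow0, aHigh0, x00, max(dx0 * scaleF, dxMin)), fn = resid,
      lower = c(-Inf, -Inf, min(xs) - diff(range(xs)), dxMin),
      upper = c(Inf, Inf, max(xs) + diff(range(xs)), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (!is.null(best) && fit$deviance >= best$deviance) next
    best <- fit
  }
  if (is.null(best)) stop("Boltzmann fit failed to converge after restarts")
  par <- best$par
  if (par[2] < par[1]) {  # swapped asymptotes: mirror the parameterization
    par <- c(par[2], par[1], par[3], par[4])
  }
  x0 <- if (rising) par[3] else -par[3]
  new("BoltzmannFit", aLow = par[1], aHigh = par[2], x0 = x0,
      dx = par[4], width1090 = 2 * par[4] * log(9),
      rss = best$deviance)
}

#' Blurriness of a tilted edge: fitted 10--90\% width
#'
#' Extracts the profile between the annotated edge endpoints and fits a
#' Boltzmann sigmoid; returns the fitted 10--90\% width in pixel units of
#' arc length along the (oblique) profile. Smaller is sharper.
#'
#' For noise robustness the profile may be averaged over several parallel
#' lines offset perpendicular to the profile direction (standard
#' slanted-edge practice); the default averages 5 lines 1 px apart.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param edge list with (row, col) endpoints \code{p0} and \code{p1}.
#' @param nLines odd number of parallel profiles to average.
#' @return Scalar 10--90\% width.
#' @export
blurrinessMetric <- function(image, edge, nLines = 5L) {
  p0 <- as.numeric(edge$p0); p1 <- as.numeric(edge$p1)
  dir <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  perp <- c(-dir[2], dir[1])
  offs <- seq_len(nLines) - (nLines + 1L) / 2
  profs <- lapply(offs, function(o)
    extractProfile(image, p0 + o * perp, p1 + o * perp))
  avg <- profs[[1]]
  avg$intensity <- Reduce(`+`, lapply(profs, `[[`, "intensity")) / nLines
  width1090(fitBoltzmann(avg))
}

#' Compute the full quality report for one arm
#'
#' @param image a \linkS4class{GrayImage}.
#' @param boxes a \link{metricBoxes}.
#' @param edge edge annotation (list p0, p1) for the blurriness profile.
#' @param arm arm label.
#' @return A \linkS4class{QualityReport} (not yet normalized).
#' @export
qualityReport <- function(image, boxes, edge, arm = "original") {
  new("QualityReport", arm = arm,
      contrast = contrastMetric(image, boxes),
      snr = snrMetric(image, boxes),
      blurriness = blurrinessMetric(image, edge),
      normalized = c(contrast = NA_real_, snr = NA_real_,
                     blurriness = NA_real_))
}

#' Normalize quality reports to the original arm
#'
#' Divides every metric by the original arm's value, so the original arm
#' reads exactly (1, 1, 1).
#'
#' @param reports list of \linkS4class{QualityReport}.
#' @param originalArm label of the reference arm.
#' @return The list with normalized slots filled.
#' @export
normalizeReports <- function(reports, originalArm = "original") {
  arms <- vapply(reports, function(r) r@arm, character(1))
  i0 <- match(originalArm, arms)
  if (is.na(i0)) stop("original arm '", originalArm, "' not present")
  ref <- reports[[i0]]
  base <- c(contrast = ref@contrast, snr = ref@snr, blurriness = ref@blurriness)
  if (any(base == 0)) stop("degenerate normalization: zero metric in original arm")
  lapply(reports, function(r) {
    r@normalized <- c(contrast = r@contrast, snr = r@snr,
                      blurriness = r@blurriness) / base
    r
  })
}

#' Match profile minima and maxima for fair visual comparison
#'
#' Affinely rescales every profile so that all share the first profile's
#' minimum and maximum.
#'
#' @param profiles list of data.frames with columns position, intensity.
#' @return List of rescaled profiles.
#' @export
profileMinMaxMatch <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1]]$intensity
  lo <- min(ref); hi <- max(ref)
  if (hi - lo <= 0) stop("degenerate reference profile (flat)")
  lapply(profiles, function(pr) {
    y <- pr$intensity
    if (max(y) - min(y) <= 0) stop("degenerate profile (flat)")
    pr$intensity <- lo + (hi - lo) * (y - min(y)) / (max(y) - min(y))
    pr
  })
}
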