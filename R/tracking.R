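## Mask-based MSSD tumor tracking: binary mask from an ROI polygon on the
## reference frame, exhaustive integer-pixel search of the mean summed
## squared difference within a fixed window, a multiple-minima
## detection-failure rule, and accuracy evaluation against feature-based
## origins.

#' Feature-based positional origin from three points
#'
#' The arithmetic mean of three manually selected feature points, used as
#' the per-frame positional origin Tm(k).
#'
#' @param points numeric 3 x 2 matrix (or list of three (row, col) pairs).
#' @return Numeric (row, col), real-valued (not rounded).
#' @export
manualOrigin <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) != 3L || ncol(points) != 2L)
    stop("exactly three (row, col) feature points are required")
  colMeans(points)
}

## Even-odd (ray casting) point-in-polygon test for pixel centers.
pointsInPolygon <- function(rows, cols, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(rows))
  j <- n
  for (i in seq_len(n)) {
    ri <- poly[i, 1]; ci <- poly[i, 2]
    rj <- poly[j, 1]; cj <- poly[j, 2]
    cross <- ((ri > rows) != (rj > rows)) &
      (cols < (cj - ci) * (rows - ri) / (rj - ri) + ci)
    inside <- xor(inside, cross & (ri != rj))
    j <- i
  }
  inside
}

#' Rasterize an ROI polygon into a binary tracking mask
#'
#' Marks every pixel whose center lies inside the polygon (even-odd rule)
#' and extracts the reference-frame intensities under the mask as the
#' matching template.
#'
#' @param referenceFrame the reference \linkS4class{GrayImage}.
#' @param roiPolygon numeric matrix of (row, col) vertices (>= 3, simple,
#'   inside the frame).
#' @param frameIndex index of the reference frame (1-based).
#' @return A \linkS4class{TumorMask}.
#' @export
buildMask <- function(referenceFrame, roiPolygon, frameIndex = 1L) {
  stopifnot(is(referenceFrame, "GrayImage"))
  poly <- as.matrix(roiPolygon)
  if (nrow(poly) < 3L || ncol(poly) != 2L)
    stop("roiPolygon needs at least 3 (row, col) vertices")
  p <- pixels(referenceFrame)
  ## vertices may sit on the outer pixel boundaries (half-integer corners)
  if (any(poly[, 1] < 0.5) || any(poly[, 1] > nrow(p) + 0.5) ||
      any(poly[, 2] < 0.5) || any(poly[, 2] > ncol(p) + 0.5))
    stop("roiPolygon must lie inside the frame")
  rr <- range(floor(poly[, 1])); cr <- range(floor(poly[, 2]))
  rows <- max(1L, rr[1]):min(nrow(p), rr[2] + 1L)
  cols <- max(1L, cr[1]):min(ncol(p), cr[2] + 1L)
  grid <- expand.grid(row = rows, col = cols)
  inside <- pointsInPolygon(grid$row, grid$col, poly)
  if (!any(inside)) stop("ROI polygon rasterizes to an empty mask")
  mask <- matrix(FALSE, nrow(p), ncol(p))
  mask[cbind(grid$row[inside], grid$col[inside])] <- TRUE
  idx <- which(mask, arr.ind = TRUE)
  new("TumorMask", mask = mask, referenceIndex = as.integer(frameIndex),
      roiPolygon = poly, referencePatch = p[mask],
      centroid = c(mean(idx[, 1]), mean(idx[, 2])))
}

#' Search window for the tracker
#'
#' @param halfWidth integer half-width in px; the default 5 spans the
#'   customary 10 x 10 px region (offsets -5..5 in each axis).
#' @return A list of class "searchWindow".
#' @export
searchWindow <- function(halfWidth = 5L) {
  halfWidth <- as.integer(halfWidth)
  if (halfWidth < 1L) stop("halfWidth must be >= 1")
  structure(list(halfWidth = halfWidth), class = "searchWindow")
}

#' Mean of summed squared differences at one offset
#'
#' The mean over masked pixels of the squared difference between the
#' reference template and the object frame shifted by an integer offset.
#' Zero iff the patches are identical under the mask.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param objectFrame a \linkS4class{GrayImage} congruent with the
#'   reference frame.
#' @param offset integer (row, col) shift of the mask footprint.
#' @return Non-negative scalar score.
#' @export
mssdScore <- function(mask, objectFrame, offset = c(0L, 0L)) {
  stopifnot(is(mask, "TumorMask"), is(objectFrame, "GrayImage"))
  p <- pixels(objectFrame)
  idx <- which(mask@mask, arr.ind = TRUE)
  r <- idx[, 1] + offset[1]; c <- idx[, 2] + offset[2]
  if (min(r) < 1L || max(r) > nrow(p) || min(c) < 1L || max(c) > ncol(p))
    stop("shifted mask footprint falls outside the object frame")
  mean((mask@referencePatch - p[cbind(r, c)])^2)
}

#' Locate the tumor in one frame by exhaustive MSSD search
#'
#' Evaluates the MSSD at every integer offset in the search window. If the
#' global minimum is attained at exactly one offset (within a relative tie
#' tolerance), the frame is detected at that offset; multiple minima mean
#' the frame is undetected. The full score surface is returned for
#' inspection.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param objectFrame a \linkS4class{GrayImage}.
#' @param window a \link{searchWindow}.
#' @param tieTol relative tolerance under which two scores count as tied.
#' @param frameIndex frame index recorded in the result.
#' @param manual feature-based origin Tm(k) for this frame (optional at
#'   this stage; needed by \link{evaluateAccuracy}).
#' @return A \linkS4class{FrameTrackResult} with position fields filled;
#'   the tracked position is the mask centroid plus the best offset.
#' @export
locateTumor <- function(mask, objectFrame, window = searchWindow(),
                        tieTol = 1e-9, frameIndex = 1L,
                        manual = c(NA_real_, NA_real_)) {
  hw <- window$halfWidth
  offs <- -hw:hw
  surface <- matrix(NA_real_, length(offs), length(offs),
                    dimnames = list(row = offs, col = offs))
  idx <- which(mask@mask, arr.ind = TRUE)
  p <- pixels(objectFrame)
  if (min(idx[, 1]) - hw < 1L || max(idx[, 1]) + hw > nrow(p) ||
      min(idx[, 2]) - hw < 1L || max(idx[, 2]) + hw > ncol(p))
    stop("search window exceeds frame bounds for this mask")
  ref <- mask@referencePatch
  for (i in seq_along(offs)) for (j in seq_along(offs)) {
    surface[i, j] <- mean((ref - p[cbind(idx[, 1] + offs[i],
                                         idx[, 2] + offs[j])])^2)
  }
  mn <- min(surface)
  ties <- which(surface <= mn + tieTol * max(mn, .Machine$double.xmin),
                arr.ind = TRUE)
  detected <- nrow(ties) == 1L
  tracked <- if (detected) {
    mask@centroid + c(offs[ties[1, 1]], offs[ties[1, 2]])
  } else c(NA_real_, NA_real_)
  new("FrameTrackResult", frame = as.integer(frameIndex), tracked = tracked,
      manual = as.numeric(manual), d = c(NA_real_, NA_real_),
      e = c(NA_real_, NA_real_), surface = surface, detected = detected)
}

#' Track a whole sequence against a reference-frame mask
#'
#' Runs \link{locateTumor} on every frame (including the reference, whose
#' tracked offset is trivially found by the same search).
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param frames list of \linkS4class{GrayImage}.
#' @param origins numeric n x 2 matrix of per-frame feature-based origins
#'   Tm(k).
#' @param window a \link{searchWindow}.
#' @param tieTol relative tie tolerance.
#' @return List of \linkS4class{FrameTrackResult}.
#' @export
trackSequence <- function(mask, frames, origins, window = searchWindow(),
                          tieTol = 1e-9) {
  stopifnot(length(frames) == nrow(origins))
  lapply(seq_along(frames), function(k)
    locateTumor(mask, frames[[k]], window, tieTol, frameIndex = k,
                manual = origins[k, ]))
}

#' Evaluate tracking accuracy against feature-based origins
#'
#' Fills d(k) = Tm(k) - Tt(k) (converted to mm via the pixel spacing) and
#' the reference-corrected error e(k) = d(k) - d(0) for every detected
#' frame. The reference frame's e is exactly (0, 0); undetected frames
#' carry no d or e.
#'
#' @param results list of \linkS4class{FrameTrackResult} from
#'   \link{trackSequence}.
#' @param pixelSpacingMM pixel spacing in mm.
#' @param referenceIndex index of the reference frame within results.
#' @return The list with d and e slots filled.
#' @export
evaluateAccuracy <- function(results, pixelSpacingMM,
                             referenceIndex = 1L) {
  ref <- results[[referenceIndex]]
  if (!ref@detected)
    stop("evaluation impossible: reference frame was not detected")
  d0 <- (ref@manual - ref@tracked) * pixelSpacingMM
  lapply(results, function(res) {
    if (res@detected) {
      res@d <- (res@manual - res@tracked) * pixelSpacingMM
      res@e <- res@d - d0
    }
    res
  })
}

#' Summarize per-axis tracking errors for one arm
#'
#' Per-axis (rows = superior--inferior, columns = left--right) mean and
#' sample standard deviation of the absolute error components |e(k)| in mm
#' over detected non-reference frames, plus detection counts.
#'
#' @param results evaluated list of \linkS4class{FrameTrackResult}.
#' @param arm arm label.
#' @param referenceIndex index of the reference frame (excluded).
#' @return A one-row data.frame: arm, meanSI, sdSI, meanLR, sdLR, nFrames,
#'   nDetected, nUndetected.
#' @export
summarizeErrors <- function(results, arm = "original", referenceIndex = 1L) {
  obj <- results[-referenceIndex]
  det <- vapply(obj, function(r) r@detected, logical(1))
  if (!any(det)) stop("empty summary: no detected non-reference frames")
  e <- t(vapply(obj[det], function(r) abs(r@e), numeric(2)))
  data.frame(arm = arm,
             meanSI = mean(e[, 1]), sdSI = stats::sd(e[, 1]),
             meanLR = mean(e[, 2]), sdLR = stats::sd(e[, 2]),
             nFrames = length(obj), nDetected = sum(det),
             nUndetected = sum(!det))
}
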