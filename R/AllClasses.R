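#' GrayImage: a 2D grayscale image with physical pixel spacing
#'
#' The central image container of the package. Pixels are stored as a
#' numeric matrix of non-negative, finite intensities in arbitrary linear
#' units; the first index is the image row (row 1 at the top), the second
#' the column. Spacing is isotropic and in millimetres. The same container
#' carries the ideal (pristine) image, the degraded observation, and every
#' enhanced arm.
#'
#' @slot pixels numeric matrix of intensities (finite, >= 0).
#' @slot spacing scalar pixel spacing in mm (> 0).
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", spacing = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (length(dim(p)) != 2L || nrow(p) < 1L || ncol(p) < 1L)
      return("pixels must be a non-empty 2D matrix")
    if (!all(is.finite(p))) return("all intensities must be finite")
    if (any(p < 0)) return("intensities must be non-negative")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      return("spacing must be a single positive number (mm)")
    TRUE
  })

#' PSFModel: a Lorentzian point spread function and its discrete kernel
#'
#' Houses the blur operator of the observation model g = Hf + eta. The
#' continuous form is the normalized Lorentzian
#' 1 / (1 + (x^2 + y^2) / lambda^2)^{3/2}; the kernel slot holds its
#' discretization at pixel centers, truncated to a square support and
#' renormalized to unit sum.
#'
#' @slot lambda Lorentzian width parameter (mm, > 0).
#' @slot kernel numeric matrix, non-negative, summing to 1, symmetric under
#'   reflection of either axis.
#' @slot supportHalfWidth integer half-width of the square support (px).
#' @slot spacing pixel spacing (mm) the kernel was sampled at.
#' @export
setClass("PSFModel",
  representation(lambda = "numeric", kernel = "matrix",
                 supportHalfWidth = "integer", spacing = "numeric"),
  validity = function(object) {
    k <- object@kernel
    if (any(k < 0)) return("kernel entries must be non-negative")
    if (abs(sum(k) - 1) > 1e-12) return("kernel must sum to 1")
    if (nrow(k) != ncol(k) || nrow(k) %% 2L != 1L)
      return("kernel must be square with odd side")
    if (max(abs(k - k[nrow(k):1, ])) > 0 || max(abs(k - k[, ncol(k):1])) > 0)
      return("kernel must be symmetric under axis reflection")
    if (object@lambda <= 0) return("lambda must be positive")
    TRUE
  })

#' BoltzmannFit: sigmoid fit to an edge profile
#'
#' Result of fitting y = aLow + (aHigh - aLow) / (1 + exp(-(x - x0)/dx))
#' to a sampled edge profile. The blurriness measure is the 10--90\% width,
#' which for this parameterization is 2 * dx * log(9) in closed form.
#'
#' @slot aLow lower asymptote.
#' @slot aHigh upper asymptote (> aLow).
#' @slot x0 inflection position (profile position units).
#' @slot dx slope parameter (> 0).
#' @slot width1090 the 10--90\% width, 2 * dx * log(9).
#' @slot rss residual sum of squares of the fit.
#' @export
setClass("BoltzmannFit",
  representation(aLow = "numeric", aHigh = "numeric", x0 = "numeric",
                 dx = "numeric", width1090 = "numeric", rss = "numeric"),
  validity = function(object) {
    if (object@aHigh <= object@aLow) return("aHigh must exceed aLow")
    if (object@dx <= 0) return("dx must be positive")
    if (abs(object@width1090 - 2 * object@dx * log(9)) >
        1e-9 * max(1, object@width1090))
      return("width1090 must equal 2 * dx * log(9)")
    TRUE
  })

#' TumorMask: binary tracking template tied to a reference frame
#'
#' A binary mask rasterized from a region-of-interest polygon drawn on the
#' reference frame, together with the reference-frame intensities under the
#' mask (the matching template) and the mask centroid, which anchors
#' reported tracked positions.
#'
#' @slot mask logical matrix, congruent with the reference frame.
#' @slot referenceIndex index of the reference frame (1-based).
#' @slot roiPolygon numeric matrix of (row, col) vertices.
#' @slot referencePatch numeric vector: reference intensities where mask is TRUE.
#' @slot centroid numeric (row, col) centroid of the mask pixels.
#' @export
setClass("TumorMask",
  representation(mask = "matrix", referenceIndex = "integer",
                 roiPolygon = "matrix", referencePatch = "numeric",
                 centroid = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    npix <- sum(object@mask)
    if (npix < 1L) return("mask must contain at least one pixel")
    if (length(object@referencePatch) != npix)
      return("referencePatch length must equal mask pixel count")
    TRUE
  })

#' FrameTrackResult: per-frame output of the MSSD tracker
#'
#' Holds the tracked position Tt(k), the manually (or synthetically)
#' selected feature-based origin Tm(k), the relative distance vector
#' d(k) = Tm(k) - Tt(k) and the reference-corrected error
#' e(k) = d(k) - d(0) (both in mm once evaluated), the full MSSD score
#' surface over the search window, and the detection flag. A frame is
#' undetected when the minimum of the score surface is attained at more
#' than one offset (within a relative tie tolerance).
#'
#' @slot frame frame index k (1-based; frame 1 is the reference).
#' @slot tracked numeric (row, col) tracked position Tt(k); NA if undetected.
#' @slot manual numeric (row, col) feature-based origin Tm(k).
#' @slot d numeric (row, col) Tm(k) - Tt(k), mm (NA until evaluated).
#' @slot e numeric (row, col) d(k) - d(0), mm (NA until evaluated/undetected).
#' @slot surface numeric matrix of MSSD scores over the search window.
#' @slot detected logical: unique global minimum found.
#' @export
setClass("FrameTrackResult",
  representation(frame = "integer", tracked = "numeric", manual = "numeric",
                 d = "numeric", e = "numeric", surface = "matrix",
                 detected = "logical"),
  validity = function(object) {
    if (length(object@tracked) != 2L || length(object@manual) != 2L)
      return("tracked and manual must be (row, col) pairs")
    if (object@detected && any(is.na(object@tracked)))
      return("detected result must carry a tracked position")
    TRUE
  })

#' QualityReport: the three image quality metrics for one arm
#'
#' Contrast (Iw - Ib)/Iw, signal-to-noise ratio Iw/sigma_b, and blurriness
#' (10--90\% edge width), raw and -- after normalization -- relative to the
#' original arm, whose normalized values are exactly 1.
#'
#' @slot arm arm label, e.g. "original", "deblurred", "clahe", "denoised".
#' @slot contrast raw contrast value.
#' @slot snr raw signal-to-noise ratio.
#' @slot blurriness raw 10--90\% edge width (profile units).
#' @slot normalized named numeric triple (contrast, snr, blurriness) divided
#'   by the original arm's values; NA before normalization.
#' @export
setClass("QualityReport",
  representation(arm = "character", contrast = "numeric", snr = "numeric",
                 blurriness = "numeric", normalized = "numeric"),
  prototype(normalized = c(contrast = NA_real_, snr = NA_real_,
                           blurriness = NA_real_)))
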