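#' Construct a GrayImage
#'
#' @param pixels numeric matrix of non-negative intensities; rows are image
#'   rows (row 1 at the top).
#' @param spacing isotropic pixel spacing in mm.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- grayImage(matrix(runif(32 * 32), 32, 32), spacing = 0.784)
#' dim(img)
#' @export
grayImage <- function(pixels, spacing = 1) {
  if (is.vector(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, spacing = as.numeric(spacing))
}

#' @describeIn grayImage pixel matrix accessor
#' @param x a GrayImage.
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @describeIn grayImage pixel spacing accessor (mm)
#' @export
setMethod("pixelSpacing", "GrayImage", function(x) x@spacing)

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage: %d x %d px, spacing %.4g mm, range [%.4g, %.4g]\n",
              d[1], d[2], object@spacing,
              min(object@pixels), max(object@pixels)))
})

#' @describeIn lorentzianPSF kernel accessor
#' @export
setMethod("psfKernel", "PSFModel", function(x) x@kernel)

#' @describeIn lorentzianPSF pixel spacing the kernel was sampled at
#' @export
setMethod("pixelSpacing", "PSFModel", function(x) x@spacing)

setMethod("show", "PSFModel", function(object) {
  cat(sprintf(
    "PSFModel: Lorentzian lambda = %.4g mm, %d x %d kernel (half-width %d px at %.4g mm)\n",
    object@lambda, nrow(object@kernel), ncol(object@kernel),
    object@supportHalfWidth, object@spacing))
})

#' @describeIn fitBoltzmann fitted 10--90\% width accessor
#' @export
setMethod("width1090", "BoltzmannFit", function(x) x@width1090)

setMethod("show", "BoltzmannFit", function(object) {
  cat(sprintf(
    "BoltzmannFit: asymptotes [%.4g, %.4g], x0 = %.4g, dx = %.4g, 10-90%% width = %.4g (rss %.3g)\n",
    object@aLow, object@aHigh, object@x0, object@dx,
    object@width1090, object@rss))
})

setMethod("show", "TumorMask", function(object) {
  cat(sprintf("TumorMask: %d px on a %d x %d reference frame (frame %d), centroid (%.2f, %.2f)\n",
              sum(object@mask), nrow(object@mask), ncol(object@mask),
              object@referenceIndex, object@centroid[1], object@centroid[2]))
})

#' @describeIn locateTumor detection flag accessor
#' @export
setMethod("isDetected", "FrameTrackResult", function(x) x@detected)

#' @describeIn locateTumor tracked (row, col) position accessor
#' @export
setMethod("trackedPosition", "FrameTrackResult", function(x) x@tracked)

#' @describeIn locateTumor MSSD surface accessor
#' @export
setMethod("scoreSurface", "FrameTrackResult", function(x) x@surface)

setMethod("show", "FrameTrackResult", function(object) {
  if (object@detected) {
    cat(sprintf("FrameTrackResult: frame %d detected at (%.1f, %.1f)",
                object@frame, object@tracked[1], object@tracked[2]))
  } else {
    cat(sprintf("FrameTrackResult: frame %d undetected (multiple minima)",
                object@frame))
  }
  if (!any(is.na(object@e)))
    cat(sprintf(", e = (%.3f, %.3f) mm", object@e[1], object@e[2]))
  cat("\n")
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport [%s]: contrast %.4g, SNR %.4g, blurriness %.4g\n",
              object@arm, object@contrast, object@snr, object@blurriness))
  if (!any(is.na(object@normalized)))
    cat(sprintf("  normalized to original: contrast %.3g, SNR %.3g, blurriness %.3g\n",
                object@normalized["contrast"], object@normalized["snr"],
                object@normalized["blurriness"]))
})
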