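#' @title Generics for portaltrack classes
#' @name portaltrack-generics
#' @keywords internal
NULL

#' Extract the pixel matrix of an image-like object
#'
#' @param x a \linkS4class{GrayImage} or \linkS4class{PSFModel}.
#' @return A numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Pixel spacing in millimetres
#'
#' @param x a \linkS4class{GrayImage} or \linkS4class{PSFModel}.
#' @return Scalar pixel spacing (mm, isotropic).
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Discretized convolution kernel of a PSF model
#'
#' @param x a \linkS4class{PSFModel}.
#' @return A numeric matrix summing to 1.
#' @export
setGeneric("psfKernel", function(x) standardGeneric("psfKernel"))

#' Fitted 10--90\% edge width
#'
#' @param x a \linkS4class{BoltzmannFit}.
#' @return Scalar width in profile position units.
#' @export
setGeneric("width1090", function(x) standardGeneric("width1090"))

#' Was the target detected in this frame?
#'
#' @param x a \linkS4class{FrameTrackResult}.
#' @return Logical scalar.
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' Tracked target position
#'
#' @param x a \linkS4class{FrameTrackResult}.
#' @return Numeric (row, col) position, or NAs when undetected.
#' @export
setGeneric("trackedPosition", function(x) standardGeneric("trackedPosition"))

#' MSSD score surface over the search window
#'
#' @param x a \linkS4class{FrameTrackResult}.
#' @return Numeric matrix of scores indexed by (row offset, col offset).
#' @export
setGeneric("scoreSurface", function(x) standardGeneric("scoreSurface"))
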