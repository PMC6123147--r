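## File interfaces: 16-bit TIFF / PNG frames and JSON annotations.

#' Write a GrayImage to TIFF or PNG
#'
#' Intensities are scaled by \code{maxIntensity} into [0, 1] and written
#' as 16-bit TIFF or PNG (by file extension). The scale and pixel spacing
#' are recorded in a JSON sidecar so reading round-trips.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param path output path ending in .tif/.tiff or .png.
#' @param maxIntensity intensity mapped to full scale; defaults to the
#'   image maximum.
#' @return Invisibly, \code{path}.
#' @export
writeGrayImage <- function(image, path, maxIntensity = max(pixels(image))) {
  stopifnot(is(image, "GrayImage"))
  if (maxIntensity <= 0) maxIntensity <- 1
  x <- pmin(pmax(pixels(image) / maxIntensity, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else stop("unsupported image format: .", ext)
  jsonlite::write_json(
    list(pixel_spacing_mm = pixelSpacing(image),
         max_intensity = maxIntensity),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GrayImage written by writeGrayImage
#'
#' @param path image path; the JSON sidecar written alongside supplies
#'   spacing and intensity scale (overridable).
#' @param spacing pixel spacing (mm) if no sidecar is present.
#' @param maxIntensity full-scale intensity if no sidecar is present.
#' @return A \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path, spacing = 1, maxIntensity = 1) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    spacing <- meta$pixel_spacing_mm
    maxIntensity <- meta$max_intensity
  }
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  grayImage(x * maxIntensity, spacing)
}

#' Write cine ground truth and annotations as JSON
#'
#' Centers are written as a frame-indexed map of [row, col]; boxes as
#' [row0, col0, row1, col1] half-open and 0-based (the on-disk
#' convention); edges as endpoint pairs.
#'
#' @param truth a truth list from \link{makeQC3Phantom} or
#'   \link{makeCineSequence}.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeGroundTruth <- function(truth, path) {
  enc <- truth
  toHalfOpen <- function(b) c(b[1] - 1L, b[2] - 1L, b[3], b[4])
  if (!is.null(enc$whiteBox)) enc$whiteBox <- toHalfOpen(enc$whiteBox)
  if (!is.null(enc$blackBox)) enc$blackBox <- toHalfOpen(enc$blackBox)
  if (!is.null(enc$centers)) {
    enc$centers <- stats::setNames(
      lapply(seq_len(nrow(truth$centers)),
             function(k) truth$centers[k, ] - 1L),
      as.character(seq_len(nrow(truth$centers)) - 1L))
  }
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations written by writeGroundTruth
#'
#' @param path JSON path.
#' @return The truth list with 1-based inclusive boxes and a centers
#'   matrix, matching the in-memory convention.
#' @export
readGroundTruth <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fromHalfOpen <- function(b) c(b[1] + 1L, b[2] + 1L, b[3], b[4])
  if (!is.null(enc$whiteBox)) enc$whiteBox <- fromHalfOpen(enc$whiteBox)
  if (!is.null(enc$blackBox)) enc$blackBox <- fromHalfOpen(enc$blackBox)
  if (!is.null(enc$centers)) {
    ord <- order(as.integer(names(enc$centers)))
    enc$centers <- do.call(rbind, enc$centers[ord]) + 1L
    rownames(enc$centers) <- NULL
  }
  enc
}
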