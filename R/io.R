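## Raster IO: thin wrappers over EBImage that standardize on h x w(
## row-major) arrays with values in [0, 1].

#' Read a photograph as an sRGB array
#'
#' Reads PNG/JPEG/TIFF into an \code{h x w x 3} array in [0, 1]. Grayscale
#' input is replicated across channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return numeric array \code{h x w x 3}.
#' @export
readImageRaster <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2, 1, 3))
}

#' Write an sRGB array as an image file
#'
#' @param image numeric array \code{h x w x 3} in [0, 1].
#' @param path output path; the extension selects the format (PNG
#'   recommended: lossless).
#' @export
writeImageRaster <- function(image, path) {
  img <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Read a binary mask
#'
#' Single-channel image; any nonzero pixel is foreground. Multi-channel
#' input uses the first channel.
#'
#' @param path mask file path.
#' @return logical matrix \code{h x w}.
#' @export
readMask <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  t(a) > 0
}

#' Write a binary mask as 0/255 single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
writeMask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path)
  invisible(path)
}

#' Luminance plane of an sRGB array
#'
#' Rec. 709 luma of the linearized channels; used for layout detection.
#'
#' @param image numeric array \code{h x w x 3} in [0, 1].
#' @return numeric matrix \code{h x w}.
#' @export
luminance <- function(image) {
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}
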