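## sRGB <-> CIELAB colorimetry and colour-space down-sampling.
##
## All conversions use the sRGB standard primaries; the reference white
## defaults to D65 / 2 degree observer (the sRGB standard). Delta E is the
## plain Euclidean distance in (L, a, b).

.WHITE_POINTS <- list(
  D65 = c(X = 0.95047, Y = 1.00000, Z = 1.08883),
  D50 = c(X = 0.96422, Y = 1.00000, Z = 0.82521)
)

.RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   3, 3, byrow = TRUE)

.lab_f <- function(t) {
  eps <- 216 / 24389
  kappa <- 24389 / 27
  ifelse(t > eps, t^(1 / 3), (kappa * t + 16) / 116)
}

.lab_finv <- function(ft) {
  eps <- 216 / 24389
  kappa <- 24389 / 27
  t3 <- ft^3
  ifelse(t3 > eps, t3, (116 * ft - 16) / kappa)
}

## Core conversion on an n x 3 matrix of sRGB values in [0, 1].
.srgb_matrix_to_lab <- function(rgb, white = "D65") {
  wp <- .WHITE_POINTS[[match.arg(white, names(.WHITE_POINTS))]]
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.RGB2XYZ)
  fx <- .lab_f(xyz[, 1] / wp["X"])
  fy <- .lab_f(xyz[, 2] / wp["Y"])
  fz <- .lab_f(xyz[, 3] / wp["Z"])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

.lab_matrix_to_srgb <- function(lab, white = "D65") {
  wp <- .WHITE_POINTS[[match.arg(white, names(.WHITE_POINTS))]]
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.lab_finv(fx) * wp["X"], .lab_finv(fy) * wp["Y"],
               .lab_finv(fz) * wp["Z"])
  lin <- xyz %*% t(solve(.RGB2XYZ))
  rgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  pmin(pmax(rgb, 0), 1)
}

#' Convert an sRGB raster to a CIELAB image
#'
#' Applies the standard sRGB gamma expansion, the sRGB-primaries RGB-to-XYZ
#' matrix, and the CIE L*a*b* transform relative to the chosen reference
#' white. Input values may be given in [0, 1] (the \pkg{EBImage} convention)
#' or as 8-bit integers 0--255; 16-bit integer input (values above 255) is
#' rescaled with a warning.
#'
#' @param image numeric array \code{h x w x 3} of sRGB values.
#' @param white reference white, \code{"D65"} (default, the sRGB standard)
#'   or \code{"D50"}.
#' @param valid optional logical \code{h x w} validity mask; invalid pixels
#'   are excluded from all downstream colour accounting. Defaults to all
#'   pixels valid.
#' @return a \linkS4class{LabImage}.
#' @examples
#' img <- array(runif(60), dim = c(4, 5, 3))
#' lab <- srgbToLab(img)
#' range(labData(lab)[, , 1])  # L in [0, 100]
#' @export
srgbToLab <- function(image, white = "D65", valid = NULL) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected a 3-channel raster (h x w x 3), got dimensions: ",
         paste(d, collapse = " x "))
  mx <- suppressWarnings(max(image, na.rm = TRUE))
  if (mx > 255) {
    warning("input looks 16-bit (max ", mx, "); rescaling by 65535")
    image <- image / 65535
  } else if (mx > 1) {
    image <- image / 255
  }
  m <- cbind(c(image[, , 1]), c(image[, , 2]), c(image[, , 3]))
  lab <- .srgb_matrix_to_lab(m, white)
  out <- array(lab, dim = d)
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(valid), d[1:2]))
    stop("validity mask dimensions must match the image")
  new("LabImage", lab = out, valid = valid)
}

#' Render CIELAB colours back to sRGB
#'
#' Inverse of \code{\link{srgbToLab}}; out-of-gamut channels are clipped to
#' [0, 1]. Used by the synthetic-fixture generator and round-trip tests.
#'
#' @param lab numeric matrix \code{n x 3} of L, a, b rows, or an
#'   \code{h x w x 3} array.
#' @param white reference white id.
#' @return sRGB values in [0, 1], same shape as the input.
#' @export
labToSrgb <- function(lab, white = "D65") {
  if (is.matrix(lab)) return(.lab_matrix_to_srgb(lab, white))
  d <- dim(lab)
  m <- .lab_matrix_to_srgb(cbind(c(lab[, , 1]), c(lab[, , 2]), c(lab[, , 3])),
                           white)
  array(m, dim = d)
}

#' Euclidean colour difference (Delta E)
#'
#' Delta E between CIELAB colours: the Euclidean distance in (L, a, b),
#' which in this space is approximately proportional to perceived colour
#' difference. Operates row-wise on matrices with recycling of a
#' single-row argument.
#'
#' @param c1,c2 numeric vectors of length 3 or \code{n x 3} matrices.
#' @return non-negative numeric vector of distances.
#' @examples
#' deltaE(c(0, 0, 0), c(0, 3, 4))  # 5
#' @export
deltaE <- function(c1, c2) {
  if (!is.matrix(c1)) c1 <- matrix(c1, ncol = 3)
  if (!is.matrix(c2)) c2 <- matrix(c2, ncol = 3)
  if (nrow(c1) == 1L && nrow(c2) > 1L) c1 <- c1[rep(1L, nrow(c2)), , drop = FALSE]
  if (nrow(c2) == 1L && nrow(c1) > 1L) c2 <- c2[rep(1L, nrow(c1)), , drop = FALSE]
  stopifnot(all(is.finite(c1)), all(is.finite(c2)))
  sqrt(rowSums((c1 - c2)^2))
}

#' Down-sample pixel colours into colour-space voxels
#'
#' Assigns every valid pixel to the cubic bin of side \code{binSize}
#' containing its Lab coordinate (floor division per axis) and records the
#' occupied bins with their geometric centres and pixel counts. Counts are
#' conserved: they sum to the number of valid pixels.
#'
#' @param lab a \linkS4class{LabImage}.
#' @param binSize bin edge length in Delta E units per axis; default 1.0
#'   (roughly the just-noticeable-difference scale).
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelize <- function(lab, binSize = 1.0) {
  stopifnot(is(lab, "LabImage"))
  if (!is.numeric(binSize) || length(binSize) != 1L || binSize <= 0)
    stop("'binSize' must be a single positive number")
  v <- c(lab@valid)
  m <- cbind(c(lab@lab[, , 1])[v], c(lab@lab[, , 2])[v], c(lab@lab[, , 3])[v])
  idx <- floor(m / binSize)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  first <- !duplicated(key)
  uk <- key[first]
  counts <- as.integer(table(factor(key, levels = uk)))
  uidx <- idx[first, , drop = FALSE]
  storage.mode(uidx) <- "integer"
  new("VoxelGrid", binSize = binSize, index = uidx,
      centers = (uidx + 0.5) * binSize, counts = counts)
}

#' Filter voxels by occupancy
#'
#' Retains only colour bins representing at least \code{minPixels} pixels.
#' This is the "min pixels" density filter used to suppress sparse colour
#' noise before hull construction (a workflow value of 20 is typical).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param minPixels minimum pixel count per retained bin (>= 0); 0 keeps
#'   every bin.
#' @return the filtered \linkS4class{VoxelGrid}.
#' @export
filterVoxels <- function(grid, minPixels = 20L) {
  stopifnot(is(grid, "VoxelGrid"), minPixels >= 0)
  keep <- grid@counts >= minPixels
  new("VoxelGrid", binSize = grid@binSize,
      index = grid@index[keep, , drop = FALSE],
      centers = grid@centers[keep, , drop = FALSE],
      counts = grid@counts[keep])
}

#' @describeIn srgbToLab extract the Lab array (\code{h x w x 3}).
#' @param x a \code{LabImage}.
#' @export
labData <- function(x) {
  stopifnot(is(x, "LabImage"))
  x@lab
}

#' @describeIn srgbToLab extract the validity mask (\code{h x w} logical).
#' @export
validMask <- function(x) {
  stopifnot(is(x, "LabImage"))
  x@valid
}

#' @describeIn voxelize accessor: voxel centres (\code{n x 3}).
#' @param grid a \code{VoxelGrid}.
#' @export
voxelCenters <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  grid@centers
}

#' @describeIn voxelize accessor: pixels per voxel.
#' @export
voxelCounts <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  grid@counts
}

## Flatten the valid pixels of a LabImage to an n x 3 matrix (helper used by
## segmentation and hull calibration).
.lab_pixels <- function(lab, sel = NULL) {
  v <- lab@valid
  if (!is.null(sel)) v <- v & sel
  cbind(c(lab@lab[, , 1])[c(v)], c(lab@lab[, , 2])[c(v)], c(lab@lab[, , 3])[c(v)])
}
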