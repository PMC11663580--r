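#' @import methods
#' @importFrom stats aggregate coef dist cutree hclust lm median quantile sd setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' CIELAB image
#'
#' Per-pixel CIELAB coordinates converted from an 8-bit sRGB photograph,
#' together with a validity mask marking pixels that carry colour information
#' downstream (pixels excluded by prior background masking are invalid).
#'
#' @slot lab numeric array \code{h x w x 3} holding L, a, b planes.
#' @slot valid logical matrix \code{h x w}; \code{FALSE} pixels contribute
#'   nothing to voxelization or segmentation.
#' @export
setClass("LabImage", representation(lab = "array", valid = "matrix"))

setValidity("LabImage", function(object) {
  d <- dim(object@lab)
  if (length(d) != 3L || d[3] != 3L)
    return("'lab' must be an h x w x 3 array")
  if (!identical(dim(object@valid), d[1:2]))
    return("'valid' mask dimensions must match the image")
  if (!is.logical(object@valid))
    return("'valid' must be logical")
  L <- object@lab[, , 1][object@valid]
  if (length(L) && any(!is.finite(c(object@lab)[rep(c(object@valid), 3)])))
    return("valid pixels must have finite Lab coordinates")
  ## small numerical headroom: the sRGB white maps to L = 100 + O(1e-5)
  ## because the standard conversion matrix rows do not sum exactly to the
  ## white point
  if (length(L) && (min(L) < -0.01 || max(L) > 100.01))
    return("L must lie in [0, 100]")
  TRUE
})

#' Colour voxel grid
#'
#' Down-sampled colour occupancy: each occupied cubic bin of side
#' \code{binSize} (Delta E units per axis) carries the bin's geometric centre
#' and the number of contributing pixels.
#'
#' @slot binSize bin edge length in Delta E units (> 0).
#' @slot index integer matrix \code{n x 3} of bin indices (floor division of
#'   each Lab axis by \code{binSize}).
#' @slot centers numeric matrix \code{n x 3}, geometric centre of each bin.
#' @slot counts integer vector, pixels per bin (all >= 1).
#' @export
setClass("VoxelGrid", representation(binSize = "numeric", index = "matrix",
                                     centers = "matrix", counts = "integer"))

setValidity("VoxelGrid", function(object) {
  n <- nrow(object@index)
  if (length(object@binSize) != 1L || object@binSize <= 0)
    return("'binSize' must be a single positive number")
  if (nrow(object@centers) != n || length(object@counts) != n)
    return("index, centers and counts must agree in length")
  if (n && any(object@counts < 1L))
    return("every occupied bin must hold at least one pixel")
  if (n && !isTRUE(all.equal(object@centers,
                             (object@index + 0.5) * object@binSize,
                             check.attributes = FALSE)))
    return("centers must be the geometric centres of their bins")
  TRUE
})

#' Target colour hull
#'
#' A target colour volume in CIELAB space: the defining vertices, the alpha
#' parameter (maximum facet edge length; 0 = no limit, i.e. the convex hull),
#' the Delta E surface threshold, and the realized triangulated surface.
#' The surface may be concave and may consist of several disjoint components.
#'
#' @slot vertices numeric matrix \code{v x 3}: the Lab vertices the hull was
#'   built from, reduced to those actually on the hull.
#' @slot alpha maximum edge length in Delta E units; 0 means unlimited.
#' @slot delta Delta E classification threshold (>= 0).
#' @slot points numeric matrix of coordinates referenced by \code{facets}.
#' @slot facets integer matrix \code{f x 3} of triangle vertex indices into
#'   \code{points}, oriented with outward normals.
#' @slot component integer vector, connected-component id per facet.
#' @slot tets integer matrix \code{t x 4}: retained tetrahedra (alpha > 0);
#'   zero rows when alpha = 0 (containment then uses facet half-spaces).
#' @export
setClass("ColorHull", representation(vertices = "matrix", alpha = "numeric",
                                     delta = "numeric", points = "matrix",
                                     facets = "matrix", component = "integer",
                                     tets = "matrix"))

setValidity("ColorHull", function(object) {
  if (object@alpha < 0) return("'alpha' must be >= 0")
  if (object@delta < 0) return("'delta' must be >= 0")
  if (ncol(object@points) != 3L) return("'points' must have 3 columns")
  if (ncol(object@facets) != 3L) return("'facets' must be triangles")
  if (nrow(object@facets) < 4L) return("a closed 3D surface needs >= 4 facets")
  if (length(object@component) != nrow(object@facets))
    return("one component id per facet required")
  edges <- rbind(object@facets[, c(1, 2)], object@facets[, c(2, 3)],
                 object@facets[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (any(table(key) %% 2L != 0L))
    return("mesh is not watertight: every edge must bound an even number of facets")
  TRUE
})

#' Indexed plate layout
#'
#' Regions of interest located by circular fiducial markers: per experimental
#' unit a 1-based index, sub-pixel centre, radius, and group membership from
#' clustering the marker centres.
#'
#' @slot units data.frame with columns \code{unit}, \code{row}, \code{col},
#'   \code{radius}, \code{group}.
#' @slot cutDistance single-linkage cut distance (pixels) used for grouping.
#' @slot ordering \code{"row-major"} or \code{"column-major"}.
#' @export
setClass("PlateLayout", representation(units = "data.frame",
                                       cutDistance = "numeric",
                                       ordering = "character"))

setValidity("PlateLayout", function(object) {
  u <- object@units
  need <- c("unit", "row", "col", "radius", "group")
  if (!all(need %in% names(u)))
    return(paste("units must have columns:", paste(need, collapse = ", ")))
  if (nrow(u) && !identical(sort(u$unit), seq_len(nrow(u))))
    return("unit indices must be unique and contiguous from 1")
  if (!object@ordering %in% c("row-major", "column-major"))
    return("ordering must be 'row-major' or 'column-major'")
  TRUE
})

setMethod("show", "LabImage", function(object) {
  d <- dim(object@lab)
  cat(sprintf("LabImage: %d x %d pixels, %d valid (%.1f%%)\n",
              d[1], d[2], sum(object@valid),
              100 * mean(object@valid)))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d occupied bins (edge %.3g dE), %d pixels\n",
              nrow(object@index), object@binSize, sum(object@counts)))
})

setMethod("show", "ColorHull", function(object) {
  cat(sprintf(
    "ColorHull: %d vertices, %d facets, %d component(s); alpha = %g, delta = %g\n",
    nrow(object@vertices), nrow(object@facets),
    length(unique(object@component)), object@alpha, object@delta))
})

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf("PlateLayout: %d units in %d group(s), %s ordering\n",
              nrow(object@units), length(unique(object@units$group)),
              object@ordering))
})
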