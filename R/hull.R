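## Target colour hulls: construction from vertex sets, containment, and
## distance-to-surface queries in CIELAB space.

## Union-find over facets sharing an undirected edge -> component labels.
.facet_components <- function(facets) {
  nf <- nrow(facets)
  parent <- seq_len(nf)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ed <- rbind(facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(1, 3)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  fid <- rep(seq_len(nf), 3L)
  for (grp in split(fid, key)) {
    if (length(grp) > 1L) {
      r <- find(grp[1])
      for (j in grp[-1]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  as.integer(match(roots, unique(roots)))
}

#' Build a target colour hull
#'
#' Constructs the triangulated boundary of a target colour volume from a set
#' of CIELAB vertices. With \code{alpha = 0} there is no edge-length limit
#' and the surface is the convex hull. With \code{alpha > 0} the vertex set
#' is Delaunay-tetrahedralized, tetrahedra having any edge longer than
#' \code{alpha} are discarded, and the boundary triangles of the retained
#' solid form the surface; this permits concave and disjoint colour volumes.
#'
#' @param vertices numeric matrix \code{n x 3} of Lab vertices (n >= 4,
#'   affinely independent).
#' @param alpha maximum tetrahedron edge length in Delta E units; 0 (the
#'   default) means unlimited, i.e. the convex hull.
#' @param delta Delta E surface threshold stored with the hull and used by
#'   \code{\link{classifyColors}}; a workflow value of 5 is typical.
#' @return a \linkS4class{ColorHull}.
#' @examples
#' tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
#' h <- buildHull(tet, alpha = 0, delta = 5)
#' nrow(hullFacets(h))  # 4 facets
#' @seealso \code{\link{hullContains}}, \code{\link{hullDistance}},
#'   \code{\link{hullFromMask}}
#' @export
buildHull <- function(vertices, alpha = 0, delta = 5) {
  if (!is.matrix(vertices) || ncol(vertices) != 3L)
    stop("'vertices' must be an n x 3 matrix of Lab coordinates")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("'alpha' must be a single number >= 0")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 ||
      !is.finite(delta))
    stop("'delta' must be a single finite number >= 0")
  P <- vertices[!duplicated(round(vertices, 12)), , drop = FALSE]
  if (nrow(P) < 4L)
    stop("degenerate hull: need at least 4 distinct vertices, got ", nrow(P))

  if (alpha == 0) {
    ch <- .chull3d(P)
    facets <- ch$facets
    tets <- matrix(integer(0), 0L, 4L)
    comp <- rep(1L, nrow(facets))
  } else {
    tets <- .delaunay3d(P)
    ## edge filter on ORIGINAL coordinates
    pairs <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                   tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
    elen <- sqrt(rowSums((P[pairs[, 1], , drop = FALSE] -
                            P[pairs[, 2], , drop = FALSE])^2))
    maxe <- apply(matrix(elen, nrow(tets), 6L), 1, max)
    keep <- maxe <= alpha
    if (!any(keep))
      stop("empty hull at alpha = ", alpha,
           ": no tetrahedron has all edges within the limit")
    tets <- tets[keep, , drop = FALSE]
    ## boundary faces: faces adjacent to exactly one retained tetrahedron
    fcs <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
    opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
    key <- apply(fcs, 1, function(f) paste(sort(f), collapse = "-"))
    cnt <- table(key)
    onb <- cnt[key] == 1L
    facets <- fcs[onb, , drop = FALSE]
    fopp <- opp[onb]
    ## orient outward: normal away from the owning tet's opposite vertex
    for (r in seq_len(nrow(facets))) {
      a <- P[facets[r, 1], ]
      nn <- .cross3(P[facets[r, 2], ] - a, P[facets[r, 3], ] - a)
      if (sum(nn * (P[fopp[r], ] - a)) > 0)
        facets[r, ] <- facets[r, c(1, 3, 2)]
    }
    comp <- .facet_components(facets)
  }
  used <- sort(unique(c(facets)))
  new("ColorHull", vertices = P[used, , drop = FALSE],
      alpha = alpha, delta = delta, points = P,
      facets = facets, component = comp, tets = tets)
}

#' Point-in-hull test
#'
#' Tests whether CIELAB points lie inside (or on) the target colour volume.
#' For a convex hull (\code{alpha = 0}) this is a facet half-space test; for
#' an alpha hull it is membership in any retained tetrahedron, so disjoint
#' components use union semantics. Boundary points count as inside.
#'
#' @param hull a \linkS4class{ColorHull}.
#' @param points numeric vector of length 3 or matrix \code{m x 3}.
#' @return logical vector of length \code{m}.
#' @export
hullContains <- function(hull, points) {
  stopifnot(is(hull, "ColorHull"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  P <- hull@points
  diam <- max(apply(P, 2, function(x) diff(range(x))))
  eps <- 1e-9 * diam
  if (hull@alpha == 0) {
    a <- P[hull@facets[, 1], , drop = FALSE]
    b <- P[hull@facets[, 2], , drop = FALSE]
    c_ <- P[hull@facets[, 3], , drop = FALSE]
    nn <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) -
                  (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
                (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) -
                  (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
                (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                  (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
    nn <- nn / sqrt(rowSums(nn^2))
    off <- rowSums(nn * a)
    sd <- points %*% t(nn) - matrix(off, nrow(points), nrow(nn), byrow = TRUE)
    return(apply(sd, 1, max) <= eps)
  }
  tets <- hull@tets
  inside <- rep(FALSE, nrow(points))
  todo <- seq_len(nrow(points))
  for (r in seq_len(nrow(tets))) {
    if (!length(todo)) break
    v0 <- P[tets[r, 1], ]
    M <- rbind(P[tets[r, 2], ] - v0, P[tets[r, 3], ] - v0, P[tets[r, 4], ] - v0)
    Minv <- tryCatch(solve(t(M)), error = function(e) NULL)
    if (is.null(Minv)) next
    q <- sweep(points[todo, , drop = FALSE], 2, v0)
    bary <- q %*% t(Minv)
    tol <- 1e-9
    hit <- bary[, 1] >= -tol & bary[, 2] >= -tol & bary[, 3] >= -tol &
      rowSums(bary) <= 1 + tol
    if (any(hit)) {
      inside[todo[hit]] <- TRUE
      todo <- todo[!hit]
    }
  }
  inside
}

#' Distance to the hull surface
#'
#' Minimum Euclidean (Delta E) distance from each query colour to the hull's
#' triangulated surface, handling closest points on facet interiors, edges,
#' and vertices. The distance is unsigned: 0 on the surface, positive both
#' inside and outside.
#'
#' @param hull a \linkS4class{ColorHull}.
#' @param points numeric vector of length 3 or matrix \code{m x 3}.
#' @return numeric vector of non-negative distances.
#' @export
hullDistance <- function(hull, points) {
  stopifnot(is(hull, "ColorHull"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  P <- hull@points
  sqrt(.min_tri_dist2(points,
                      P[hull@facets[, 1], , drop = FALSE],
                      P[hull@facets[, 2], , drop = FALSE],
                      P[hull@facets[, 3], , drop = FALSE]))
}

#' Classify colours against a target hull
#'
#' A colour is target if it lies within the hull or within the hull's
#' \code{delta} (Delta E) of its surface.
#'
#' @param hull a \linkS4class{ColorHull}.
#' @param points numeric vector of length 3 or matrix \code{m x 3}.
#' @param delta optional override of the hull's stored threshold.
#' @return logical vector: \code{TRUE} for target colours.
#' @export
classifyColors <- function(hull, points, delta = NULL) {
  stopifnot(is(hull, "ColorHull"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  if (is.null(delta)) delta <- hull@delta
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 ||
      !is.finite(delta))
    stop("'delta' must be a single finite number >= 0")
  inside <- hullContains(hull, points)
  if (all(inside)) return(inside)
  near <- hullDistance(hull, points[!inside, , drop = FALSE]) <= delta
  inside[!inside] <- near
  inside
}

#' Automated hull calibration from a labelled mask
#'
#' Builds a target hull from the colours under a supplied foreground mask:
#' masked pixels are voxelized, bins with fewer than \code{minPixels} pixels
#' are dropped, and the surviving voxel centres become candidate vertices for
#' hull construction at the given \code{alpha}.
#'
#' @param lab a \linkS4class{LabImage}.
#' @param mask logical matrix matching the image dimensions; \code{TRUE} =
#'   foreground.
#' @param minPixels occupancy filter applied to candidate voxels.
#' @param alpha maximum edge length for hull construction (0 = convex hull).
#' @param delta Delta E threshold stored with the resulting hull.
#' @param binSize voxel edge length in Delta E units.
#' @return a \linkS4class{ColorHull}.
#' @export
hullFromMask <- function(lab, mask, minPixels = 20L, alpha = 0, delta = 5,
                         binSize = 1.0) {
  stopifnot(is(lab, "LabImage"))
  if (!identical(dim(mask), dim(lab@valid)))
    stop("mask dimensions must match the image")
  sel <- lab@valid & mask
  if (!any(sel))
    stop("degenerate hull: the mask selects no valid pixels")
  sub <- new("LabImage", lab = lab@lab, valid = sel)
  grid <- filterVoxels(voxelize(sub, binSize), minPixels)
  if (nrow(grid@centers) < 4L)
    stop("degenerate hull: only ", nrow(grid@centers),
         " voxels survive the min-pixels filter (need >= 4)")
  buildHull(grid@centers, alpha = alpha, delta = delta)
}

#' Merge selected vertices with priors
#'
#' Row-wise deduplicated union of a selected vertex set and a prior vertex
#' set, preserving first-seen order (selected first). Priors carry vertex
#' selections across images or from a configuration file so a hull can be
#' generalized over an image series.
#'
#' @param selected,priors numeric matrices \code{n x 3} (either may have 0
#'   rows).
#' @return numeric matrix of unique vertices.
#' @export
mergePriors <- function(selected, priors) {
  if (is.null(selected)) selected <- matrix(numeric(0), 0L, 3L)
  if (is.null(priors)) priors <- matrix(numeric(0), 0L, 3L)
  if (!is.matrix(selected)) selected <- matrix(selected, ncol = 3)
  if (!is.matrix(priors)) priors <- matrix(priors, ncol = 3)
  all_ <- rbind(selected, priors)
  all_[!duplicated(all_), , drop = FALSE]
}

#' @describeIn buildHull hull vertices actually on the surface
#'   (\code{v x 3}).
#' @param hull a \code{ColorHull}.
#' @export
hullVertices <- function(hull) {
  stopifnot(is(hull, "ColorHull"))
  hull@vertices
}

#' @describeIn buildHull facet index triples (\code{f x 3}) into
#'   \code{hullPoints}.
#' @export
hullFacets <- function(hull) {
  stopifnot(is(hull, "ColorHull"))
  hull@facets
}

#' @describeIn buildHull coordinates referenced by the facets.
#' @export
hullPoints <- function(hull) {
  stopifnot(is(hull, "ColorHull"))
  hull@points
}

#' @describeIn buildHull connected-component id per facet.
#' @export
hullComponents <- function(hull) {
  stopifnot(is(hull, "ColorHull"))
  hull@component
}

#' @describeIn buildHull enclosed volume (divergence theorem over the
#'   outward-oriented facets; summed over components).
#' @export
hullVolume <- function(hull) {
  stopifnot(is(hull, "ColorHull"))
  .mesh_volume(hull@points, hull@facets)
}
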