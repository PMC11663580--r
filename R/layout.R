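## Plate-layout detection: circular fiducial markers found by a circular
## Hough transform, grouped by single-linkage clustering of their centres,
## and assigned 1-based indices in reading order.

#' Detect circular markers by Hough transform
#'
#' Runs a gradient-directed circular Hough transform over the luminance
#' edge map: each strong-gradient pixel votes for candidate centres at every
#' radius in \code{rMin:rMax} along both gradient directions (so marker
#' polarity does not matter). The \code{expectedN} highest-scoring
#' non-overlapping circles (centre separation > \code{rMin}) are returned
#' with sub-pixel centres.
#'
#' @param gray numeric matrix \code{h x w}, luminance in [0, 1].
#' @param rMin,rMax radius search range in pixels (\code{rMin <= rMax}).
#' @param expectedN number of markers to find (>= 1).
#' @param edgeQuantile gradient-magnitude threshold as a fraction of the
#'   maximum; pixels below it do not vote.
#' @param minScore minimum accumulator score, in units of full circles of
#'   edge support (a clean annulus scores about 2: inner and outer edge).
#'   Peaks below it are stray vote pile-ups, not circles.
#' @return data.frame with columns \code{row}, \code{col} (sub-pixel centre),
#'   \code{radius}, \code{score}, ordered by decreasing score.
#' @export
detectCircles <- function(gray, rMin, rMax, expectedN,
                          edgeQuantile = 0.3, minScore = 1) {
  stopifnot(is.matrix(gray), rMin <= rMax, rMin >= 2, expectedN >= 1)
  h <- nrow(gray); w <- ncol(gray)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
  gc[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  thr <- edgeQuantile * max(mag)
  edge <- which(mag > thr & mag > 0)
  radii <- seq.int(floor(rMin), ceiling(rMax))
  found <- data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), score = numeric(0))
  if (length(edge) == 0L) {
    if (expectedN > 0)
      stop("circle detection found 0 of ", expectedN,
           " expected circles (no edges above threshold)")
  }
  ei <- (edge - 1L) %% h + 1L
  ej <- (edge - 1L) %/% h + 1L
  ur <- gr[edge] / mag[edge]
  uc <- gc[edge] / mag[edge]
  acc <- array(0L, dim = c(h, w, length(radii)))
  for (k in seq_along(radii)) {
    r <- radii[k]
    cr <- c(round(ei + r * ur), round(ei - r * ur))
    cc <- c(round(ej + r * uc), round(ej - r * uc))
    ok <- cr >= 1 & cr <= h & cc >= 1 & cc <= w
    tab <- tabulate((cc[ok] - 1L) * h + cr[ok], nbins = h * w)
    acc[, , k] <- acc[, , k] + matrix(tab, h, w)
  }
  ## 3x3 box smoothing per radius slice to consolidate rounded votes
  sm <- acc
  for (k in seq_along(radii)) {
    a <- acc[, , k]
    p <- matrix(0, h + 2L, w + 2L)
    p[2:(h + 1), 2:(w + 1)] <- a
    s <- p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
      p[2:(h + 1), 1:w] + p[2:(h + 1), 2:(w + 1)] + p[2:(h + 1), 3:(w + 2)] +
      p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
    sm[, , k] <- s
  }
  ## centres are located on the radius-summed accumulator (dense and
  ## symmetric for an annulus, whose inner and outer edges vote at
  ## different radii); the radius is then the vote-weighted mean over
  ## slices at the refined centre.
  total <- matrix(0, h, w)
  for (k in seq_along(radii)) total <- total + sm[, , k]
  suppressed <- matrix(FALSE, h, w)
  while (nrow(found) < expectedN) {
    sc <- total
    sc[suppressed] <- -Inf
    pk <- which.max(sc)
    if (!is.finite(sc[pk])) break
    pi0 <- (pk - 1L) %% h + 1L
    pj0 <- (pk - 1L) %/% h + 1L
    ri <- max(2L, min(h - 1L, pi0)); rj <- max(2L, min(w - 1L, pj0))
    nb <- total[(ri - 1L):(ri + 1L), (rj - 1L):(rj + 1L)]
    tot <- sum(nb)
    ctr_r <- sum(nb * matrix((ri - 1L):(ri + 1L), 3, 3)) / tot
    ctr_c <- sum(nb * matrix((rj - 1L):(rj + 1L), 3, 3, byrow = TRUE)) / tot
    vk <- sm[pi0, pj0, ]
    rad <- sum(vk * radii) / sum(vk)
    score <- sum(vk) / (2 * pi * rad)
    if (score < minScore) break
    ## sub-pixel refinement: algebraic (Kasa) circle fit to the edge pixels
    ## in an annulus around the rough detection
    ## the annulus must cover the marker's inner and outer edge completely
    ## (a clipped edge biases the fit), hence the generous half-width
    for (pass in 1:2) {
      ann <- sqrt((ei - ctr_r)^2 + (ej - ctr_c)^2)
      sel <- abs(ann - rad) <= 4
      if (sum(sel) < 10L) break
      x <- ei[sel]; y <- ej[sel]
      A <- cbind(2 * x, 2 * y, 1)
      z <- x^2 + y^2
      co <- tryCatch(qr.solve(A, z), error = function(e) NULL)
      if (is.null(co)) break
      ctr_r <- co[1]; ctr_c <- co[2]
      rad <- sqrt(max(co[3] + co[1]^2 + co[2]^2, 0))
    }
    found <- rbind(found, data.frame(row = ctr_r, col = ctr_c,
                                     radius = rad, score = score))
    ## suppress candidates within rMin of this centre
    d2 <- outer((seq_len(h) - ctr_r)^2, (seq_len(w) - ctr_c)^2, "+")
    suppressed <- suppressed | (d2 <= rMin^2)
  }
  if (nrow(found) < expectedN)
    stop("circle detection found ", nrow(found), " of ", expectedN,
         " expected circles")
  found[order(-found$score, found$row, found$col), , drop = FALSE]
}

#' Group marker centres by single-linkage clustering
#'
#' Agglomerative single-linkage clustering of circle centres, cut at
#' \code{cutDistance} pixels; the number of groups is emergent.
#'
#' @param centers numeric matrix or data.frame with columns \code{row},
#'   \code{col}.
#' @param cutDistance linkage cut height in pixels (> 0).
#' @return integer vector of group labels (arbitrary but stable ids).
#' @export
clusterCenters <- function(centers, cutDistance) {
  stopifnot(cutDistance > 0)
  xy <- cbind(centers[, "row"], centers[, "col"])
  n <- nrow(xy)
  if (n == 1L) return(1L)
  hc <- hclust(dist(xy), method = "single")
  as.integer(cutree(hc, h = cutDistance))
}

## Band a coordinate vector: values within `tol` of the running band are the
## same row (or column). Returns band ids in increasing coordinate order.
.bands <- function(x, tol) {
  ord <- order(x)
  b <- integer(length(x))
  band <- 1L
  ref <- x[ord[1]]
  for (i in seq_along(ord)) {
    if (x[ord[i]] - ref > tol) {
      band <- band + 1L
      ref <- x[ord[i]]
    }
    b[ord[i]] <- band
  }
  b
}

.median_nn_spacing <- function(xy) {
  n <- nrow(xy)
  if (n < 2L) return(Inf)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  median(apply(d, 1, min))
}

#' Assign indexed regions of interest
#'
#' Orders groups by their centroid (top-to-bottom bands, then left-to-right)
#' and, within each group, orders units row-major (or column-major) with a
#' banding tolerance of half the median nearest-neighbour spacing, then
#' assigns unit indices 1..N across groups in group order.
#'
#' @param circles data.frame with columns \code{row}, \code{col},
#'   \code{radius} (as returned by \code{\link{detectCircles}}).
#' @param groups integer group labels from \code{\link{clusterCenters}}, or
#'   \code{NULL} for a single group.
#' @param ordering \code{"row-major"} (default) or \code{"column-major"}.
#' @param cutDistance the cut distance used for grouping (stored for
#'   provenance; \code{NA} when groups were supplied directly).
#' @return a \linkS4class{PlateLayout}.
#' @export
indexLayout <- function(circles, groups = NULL,
                        ordering = c("row-major", "column-major"),
                        cutDistance = NA_real_) {
  ordering <- match.arg(ordering)
  n <- nrow(circles)
  if (n == 0L) stop("no circles to index")
  if (is.null(groups)) groups <- rep(1L, n)
  stopifnot(length(groups) == n)
  ## deterministic base order regardless of input order
  base <- order(circles$row, circles$col, circles$radius)
  circles <- circles[base, , drop = FALSE]
  groups <- groups[base]

  cent <- cbind(tapply(circles$row, groups, mean),
                tapply(circles$col, groups, mean))
  gid <- as.integer(rownames(cent))
  gtol <- 0.5 * .median_nn_spacing(cent)
  gband <- .bands(cent[, 1], gtol)
  gorder <- gid[order(gband, cent[, 2])]

  units <- NULL
  idx <- 1L
  for (gpos in seq_along(gorder)) {
    g <- gorder[gpos]
    sub <- circles[groups == g, , drop = FALSE]
    tol <- 0.5 * .median_nn_spacing(cbind(sub$row, sub$col))
    if (ordering == "row-major") {
      band <- .bands(sub$row, tol)
      ord <- order(band, sub$col, sub$radius)
    } else {
      band <- .bands(sub$col, tol)
      ord <- order(band, sub$row, sub$radius)
    }
    sub <- sub[ord, , drop = FALSE]
    units <- rbind(units, data.frame(unit = idx + seq_len(nrow(sub)) - 1L,
                                     row = sub$row, col = sub$col,
                                     radius = sub$radius, group = gpos))
    idx <- idx + nrow(sub)
  }
  rownames(units) <- NULL
  new("PlateLayout", units = units, cutDistance = as.numeric(cutDistance),
      ordering = ordering)
}

#' One-call layout detection
#'
#' Convenience wrapper: \code{\link{detectCircles}} on the luminance image,
#' \code{\link{clusterCenters}}, then \code{\link{indexLayout}}.
#'
#' @inheritParams detectCircles
#' @param cutDistance single-linkage cut distance in pixels.
#' @param ordering \code{"row-major"} or \code{"column-major"}.
#' @return a \linkS4class{PlateLayout}.
#' @export
detectLayout <- function(gray, rMin, rMax, expectedN, cutDistance,
                         ordering = c("row-major", "column-major")) {
  ordering <- match.arg(ordering)
  circles <- detectCircles(gray, rMin, rMax, expectedN)
  groups <- clusterCenters(circles, cutDistance)
  indexLayout(circles, groups, ordering, cutDistance = cutDistance)
}

#' Fixed layout from explicit unit positions
#'
#' Builds a \linkS4class{PlateLayout} from user-supplied unit positions,
#' bypassing detection. Groups are taken from a \code{group} column when
#' present, otherwise from clustering at \code{cutDistance}, otherwise all
#' units form one group. Units are re-indexed in reading order.
#'
#' @param units data.frame with columns \code{row}, \code{col},
#'   \code{radius}, optional \code{group}.
#' @param cutDistance optional grouping cut distance in pixels.
#' @param ordering \code{"row-major"} or \code{"column-major"}.
#' @return a \linkS4class{PlateLayout}.
#' @export
fixedLayout <- function(units, cutDistance = NULL,
                        ordering = c("row-major", "column-major")) {
  ordering <- match.arg(ordering)
  if (!is.null(units$group)) {
    groups <- as.integer(units$group)
  } else if (!is.null(cutDistance)) {
    groups <- clusterCenters(units, cutDistance)
  } else {
    groups <- rep(1L, nrow(units))
  }
  indexLayout(units, groups, ordering,
              cutDistance = if (is.null(cutDistance)) NA_real_ else cutDistance)
}

#' Rasterize regions of interest
#'
#' Labels every pixel within \code{radius + dilation} of a unit's centre
#' with that unit's index; pixels reachable from several units go to the
#' nearest centre. Per-unit overlap flags (another unit's disc touched this
#' unit's pixels) are attached as \code{attr(, "overlap")}.
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @param dims integer \code{c(h, w)} of the target raster.
#' @param dilation extra radius in pixels added to every unit (>= 0).
#' @return integer matrix \code{h x w}; 0 = unassigned.
#' @export
roiMask <- function(layout, dims, dilation = 0) {
  stopifnot(is(layout, "PlateLayout"), length(dims) == 2L, dilation >= 0)
  u <- layout@units
  h <- dims[1]; w <- dims[2]
  lab <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  reach <- matrix(0L, h, w)
  for (k in seq_len(nrow(u))) {
    d2 <- outer((seq_len(h) - u$row[k])^2, (seq_len(w) - u$col[k])^2, "+")
    within <- d2 <= (u$radius[k] + dilation)^2
    reach <- reach + within
    claim <- within & (d2 < best)
    lab[claim] <- u$unit[k]
    best[claim] <- d2[claim]
  }
  overlap <- vapply(u$unit, function(i) any(reach > 1L & lab == i),
                    logical(1))
  attr(lab, "overlap") <- setNames(overlap, u$unit)
  lab
}

#' @describeIn indexLayout accessor: the per-unit table (\code{unit},
#'   \code{row}, \code{col}, \code{radius}, \code{group}).
#' @param layout a \code{PlateLayout}.
#' @export
layoutUnits <- function(layout) {
  stopifnot(is(layout, "PlateLayout"))
  layout@units
}
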