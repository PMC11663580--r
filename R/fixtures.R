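## Synthetic fixtures with known ground truth: multiplexed image series of
## growing colour blobs inside circular fiducial markers, plus labelled
## colour clouds for direct geometry tests. Everything is generated in
## memory from a seeded spec; no external data are needed.

.default_hull_vertices <- function() {
  ## a green tetrahedron comfortably inside the sRGB gamut
  rbind(c(35, -40, 20), c(60, -25, 45), c(32, -18, 8), c(55, -48, 42))
}

#' Synthetic-fixture specification
#'
#' Fully determines a synthetic image series given the seed: canvas and
#' layout geometry, the ground-truth target colour hull and how tightly blob
#' colours sample its interior, the background colour distribution and its
#' guaranteed Delta E separation margin, and per-unit exponential growth
#' parameters.
#'
#' @param seed RNG seed; the entire series is reproducible from it.
#' @param rows,cols units per group block.
#' @param groups number of group blocks (stacked vertically).
#' @param spacing unit grid pitch in pixels.
#' @param markerRadius fiducial ring radius in pixels.
#' @param hullVertices ground-truth hull vertex matrix (Lab).
#' @param delta Delta E threshold carried into the truth hull (default 5).
#' @param spread blob colours are drawn uniformly in the hull, then shrunk
#'   by this factor towards the hull centroid; < 1 keeps them strictly
#'   interior so 8-bit quantization cannot push them across the surface.
#' @param bgMean,bgSpread background Lab mean and half-width of its uniform
#'   spread per axis.
#' @param margin required minimum Delta E from any background or marker
#'   colour to the hull surface (default 3 * delta).
#' @param jitter maximum absolute position jitter (pixels, integer offsets)
#'   applied independently to each unit centre.
#' @param A0 initial blob area in pixels (recycled over units).
#' @param r relative growth rate in day^-1 (recycled over units).
#' @param sigma multiplicative log-normal area noise SD (0 = noiseless).
#' @param nTimepoints number of images in the series.
#' @param dt days between consecutive images.
#' @param holeArea if > 0, a hole of about this many pixels is punched in
#'   every blob (the truth mask keeps the blob solid, so raw segmentation
#'   disagrees until holes are filled).
#' @param debrisArea if > 0, specks of target colour of about this many
#'   pixels are scattered in the background (absent from the truth mask).
#' @return a list of class \code{FixtureSpec}.
#' @export
fixtureSpec <- function(seed = 1L, rows = 2L, cols = 3L, groups = 2L,
                        spacing = 70L, markerRadius = 16L,
                        hullVertices = .default_hull_vertices(),
                        delta = 5, spread = 0.6,
                        bgMean = c(30, 8, 18), bgSpread = c(4, 4, 4),
                        margin = 3 * delta, jitter = 0,
                        A0 = 120, r = 0.2, sigma = 0,
                        nTimepoints = 6L, dt = 1,
                        holeArea = 0L, debrisArea = 0L) {
  n <- rows * cols * groups
  spec <- list(seed = as.integer(seed), rows = rows, cols = cols,
               groups = groups, spacing = spacing,
               markerRadius = markerRadius, hullVertices = hullVertices,
               delta = delta, spread = spread, bgMean = bgMean,
               bgSpread = bgSpread, margin = margin, jitter = jitter,
               A0 = rep_len(A0, n), r = rep_len(r, n), sigma = sigma,
               nTimepoints = as.integer(nTimepoints), dt = dt,
               holeArea = holeArea, debrisArea = debrisArea)
  class(spec) <- "FixtureSpec"
  spec
}

## Ground-truth unit centres, row-major across vertically stacked group
## blocks (the same reading order the layout indexer uses).
.fixture_centers <- function(spec) {
  s <- spec$spacing
  marg <- round(s / 2) + spec$markerRadius
  blockH <- (spec$rows - 1L) * s
  gap <- 2L * s
  units <- NULL
  idx <- 1L
  for (g in seq_len(spec$groups)) {
    y0 <- marg + (g - 1L) * (blockH + gap)
    for (i in seq_len(spec$rows)) for (j in seq_len(spec$cols)) {
      units <- rbind(units, data.frame(
        unit = idx, row = y0 + (i - 1L) * s,
        col = marg + (j - 1L) * s, radius = spec$markerRadius, group = g))
      idx <- idx + 1L
    }
  }
  if (spec$jitter > 0) {
    units$row <- units$row + sample(-spec$jitter:spec$jitter, nrow(units),
                                    replace = TRUE)
    units$col <- units$col + sample(-spec$jitter:spec$jitter, nrow(units),
                                    replace = TRUE)
  }
  h <- marg + (spec$groups - 1L) * (blockH + gap) + blockH + marg
  w <- marg + (spec$cols - 1L) * s + marg
  list(units = units, dims = c(h, w))
}

## Uniform sample inside a simplex hull (Dirichlet weights over the first 4
## vertices works for the default tetrahedron; general hulls fall back to
## rejection from the bounding box).
.sample_in_hull <- function(n, hull, shrink) {
  V <- hull@vertices
  ctr <- colMeans(V)
  if (nrow(V) == 4L) {
    w <- matrix(-log(runif(4L * n)), n, 4L)
    w <- w / rowSums(w)
    pts <- w %*% V
  } else {
    lo <- apply(V, 2, min); hi <- apply(V, 2, max)
    pts <- matrix(NA_real_, n, 3L)
    got <- 0L
    while (got < n) {
      cand <- cbind(runif(2L * n, lo[1], hi[1]), runif(2L * n, lo[2], hi[2]),
                    runif(2L * n, lo[3], hi[3]))
      cand <- cand[hullContains(hull, cand), , drop = FALSE]
      take <- min(nrow(cand), n - got)
      if (take > 0) {
        pts[(got + 1L):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
  }
  sweep(sweep(pts, 2, ctr) * shrink, 2, ctr, "+")
}

## Render Lab colours to an 8-bit-quantized sRGB plane set.
.quantize_srgb <- function(m) round(pmin(pmax(m, 0), 1) * 255) / 255

#' Generate a synthetic image series with ground truth
#'
#' Renders \code{nTimepoints} photographs of a plate of growing blobs: white
#' fiducial rings at grid positions, per-unit blobs of area
#' \code{A0 * exp(r * t)} (times optional log-normal noise) filled with
#' colours sampled strictly inside the truth hull, and background sampled at
#' least \code{margin} Delta E outside it. All colours are quantized to
#' 8-bit sRGB before use, so writing the frames to PNG and reading them back
#' is lossless. Truth areas are pixel counts from the generator's own
#' rendering bookkeeping, and the truth RGR is the generator's own
#' closed-form least-squares slope on those counts -- independent of the
#' analysis pipeline.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list with \code{images} (list of \code{h x w x 3} sRGB arrays),
#'   \code{masks} (list of truth logical masks), \code{times} (days),
#'   \code{layout} (truth unit table), \code{dims}, \code{hull} (truth
#'   \linkS4class{ColorHull}), \code{areas} (truth per-unit/timepoint pixel
#'   counts), \code{rgr} (per-unit truth slope fit on the counts), and
#'   \code{nominalR} (the generating rates).
#' @export
makeImageSeries <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  hull <- buildHull(spec$hullVertices, alpha = 0, delta = spec$delta)
  lay <- .fixture_centers(spec)
  u <- lay$units; dims <- lay$dims
  h <- dims[1]; w <- dims[2]
  nU <- nrow(u)
  times <- (seq_len(spec$nTimepoints) - 1L) * spec$dt
  ringThick <- 3
  wobble <- 0.15
  maxA <- max(spec$A0 * exp(spec$r * max(times))) * exp(3 * spec$sigma)
  maxRb <- sqrt(maxA / pi) * (1 + wobble)
  if (maxRb > spec$markerRadius - ringThick / 2 - 1)
    stop("infeasible geometry: blobs (max radius ", round(maxRb, 1),
         " px) would exceed their marker ring (inner radius ",
         spec$markerRadius - ringThick / 2, " px)")

  ## margin guarantee: the background cuboid and the marker colour must stay
  ## 'margin' outside the hull. Distance to a convex hull is a convex
  ## function, so its minimum over the cuboid lies on the surface; a 2-dE
  ## surface grid plus Lipschitz headroom bounds it.
  gr <- lapply(1:3, function(k) {
    lo <- spec$bgMean[k] - spec$bgSpread[k]
    hi <- spec$bgMean[k] + spec$bgSpread[k]
    seq(lo, hi, length.out = max(2L, ceiling((hi - lo) / 2) + 1L))
  })
  box <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
  onSurf <- apply(box, 1, function(p) any(abs(p - spec$bgMean) >=
                                            spec$bgSpread - 1e-9))
  probe <- rbind(box[onSurf, , drop = FALSE], c(96, 0, 0))
  cont <- hullContains(hull, probe)
  dmin <- if (all(cont)) 0 else
    min(hullDistance(hull, probe[!cont, , drop = FALSE]))
  if (any(cont) || dmin < spec$margin + 3)
    stop("infeasible geometry: background/marker colours come within ",
         round(dmin, 1), " dE of the hull surface (need margin ",
         spec$margin, " + 3 dE grid/quantization headroom)")

  phase <- runif(nU, 0, 2 * pi)
  noise <- matrix(if (spec$sigma > 0)
    rnorm(nU * length(times), 0, spec$sigma) else 0, nU, length(times))

  images <- vector("list", length(times))
  masks <- vector("list", length(times))
  areas <- NULL
  rowIdx <- matrix(rep(seq_len(h), w), h, w)
  colIdx <- matrix(rep(seq_len(w), each = h), h, w)

  for (ti in seq_along(times)) {
    ## background
    npx <- h * w
    bg <- cbind(runif(npx, spec$bgMean[1] - spec$bgSpread[1],
                      spec$bgMean[1] + spec$bgSpread[1]),
                runif(npx, spec$bgMean[2] - spec$bgSpread[2],
                      spec$bgMean[2] + spec$bgSpread[2]),
                runif(npx, spec$bgMean[3] - spec$bgSpread[3],
                      spec$bgMean[3] + spec$bgSpread[3]))
    rgb <- labToSrgb(bg)
    frame <- array(rgb, dim = c(h, w, 3))
    mask <- matrix(FALSE, h, w)

    for (k in seq_len(nU)) {
      cy <- u$row[k]; cx <- u$col[k]
      ## fiducial ring (bright, slightly noisy white)
      d <- sqrt((rowIdx - cy)^2 + (colIdx - cx)^2)
      ring <- abs(d - spec$markerRadius) <= ringThick / 2
      nr <- sum(ring)
      ringLab <- cbind(runif(nr, 94, 98), runif(nr, -1, 1), runif(nr, -1, 1))
      ringRgb <- labToSrgb(ringLab)
      for (ch in 1:3) {
        pl <- frame[, , ch]; pl[ring] <- ringRgb[, ch]; frame[, , ch] <- pl
      }
      ## blob
      A <- spec$A0[k] * exp(spec$r[k] * times[ti]) * exp(noise[k, ti])
      r0 <- sqrt(A / pi)
      th <- atan2(rowIdx - cy, colIdx - cx)
      blob <- d <= r0 * (1 + wobble * sin(3 * th + phase[k]))
      if (spec$holeArea > 0) {
        hs <- max(1L, round(sqrt(spec$holeArea)))
        hole <- abs(rowIdx - cy) <= (hs - 1) / 2 & abs(colIdx - cx) <= (hs - 1) / 2
        blobDrawn <- blob & !hole
      } else blobDrawn <- blob
      nb <- sum(blobDrawn)
      blobLab <- .sample_in_hull(nb, hull, spec$spread)
      blobRgb <- labToSrgb(blobLab)
      for (ch in 1:3) {
        pl <- frame[, , ch]; pl[blobDrawn] <- blobRgb[, ch]; frame[, , ch] <- pl
      }
      if (spec$holeArea > 0) {
        ## hole pixels carry background colour; truth keeps the solid blob
        nh <- sum(blob & !blobDrawn)
        if (nh > 0) {
          holeLab <- cbind(runif(nh, spec$bgMean[1] - spec$bgSpread[1],
                                 spec$bgMean[1] + spec$bgSpread[1]),
                          runif(nh, spec$bgMean[2] - spec$bgSpread[2],
                                spec$bgMean[2] + spec$bgSpread[2]),
                          runif(nh, spec$bgMean[3] - spec$bgSpread[3],
                                spec$bgMean[3] + spec$bgSpread[3]))
          holeRgb <- labToSrgb(holeLab)
          for (ch in 1:3) {
            pl <- frame[, , ch]
            pl[blob & !blobDrawn] <- holeRgb[, ch]
            frame[, , ch] <- pl
          }
        }
      }
      mask <- mask | blob
      areas <- rbind(areas, data.frame(unit = k, group = u$group[k],
                                       time = times[ti], area_px = sum(blob)))
    }

    ## debris: target-coloured specks in the background, never in the truth
    if (spec$debrisArea > 0) {
      ds <- max(1L, round(sqrt(spec$debrisArea)))
      for (k in seq_len(nU)) {
        dy <- u$row[k] + round(spec$spacing / 2)
        dx <- u$col[k] + round(spec$spacing / 2)
        if (dy + ds > h - 1 || dx + ds > w - 1) next
        spk <- rowIdx >= dy & rowIdx < dy + ds & colIdx >= dx & colIdx < dx + ds
        nsk <- sum(spk)
        spkRgb <- labToSrgb(.sample_in_hull(nsk, hull, spec$spread))
        for (ch in 1:3) {
          pl <- frame[, , ch]; pl[spk] <- spkRgb[, ch]; frame[, , ch] <- pl
        }
      }
    }

    for (ch in 1:3) frame[, , ch] <- .quantize_srgb(frame[, , ch])
    images[[ti]] <- frame
    masks[[ti]] <- mask
  }

  ## truth RGR: the generator's own closed-form OLS on its pixel counts
  rgr <- do.call(rbind, lapply(seq_len(nU), function(k) {
    a <- areas[areas$unit == k, ]
    y <- log(a$area_px); t <- a$time
    sl <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    data.frame(unit = k, group = u$group[k], rgr = sl,
               intercept = mean(y) - sl * mean(t))
  }))

  list(images = images, masks = masks, times = times, layout = u,
       dims = dims, hull = hull, areas = areas, rgr = rgr,
       nominalR = spec$r)
}

#' Labelled colour clouds at known distances from a hull
#'
#' Builds query points with analytically known relationships to a hull:
#' facet barycenters offset outward along facet normals by \code{offset}
#' (distance exactly \code{offset} for small offsets), hull vertices
#' (distance 0), and interior points pulled toward the hull centroid
#' (contained).
#'
#' @param hull a \linkS4class{ColorHull}.
#' @param offset outward offset in Delta E units (small relative to facet
#'   size so the offset facet remains the nearest feature).
#' @return list of matrices \code{outside} (with \code{attr "distance"}),
#'   \code{vertices}, \code{interior}.
#' @export
makeColorCloud <- function(hull, offset = 0.5) {
  P <- hull@points
  f <- hull@facets
  a <- P[f[, 1], , drop = FALSE]
  b <- P[f[, 2], , drop = FALSE]
  c_ <- P[f[, 3], , drop = FALSE]
  bary <- (a + b + c_) / 3
  nn <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) -
                (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) -
                (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  nn <- nn / sqrt(rowSums(nn^2))
  outside <- bary + offset * nn
  attr(outside, "distance") <- rep(offset, nrow(outside))
  ctr <- colMeans(hull@vertices)
  interior <- sweep(sweep(bary, 2, ctr) * 0.5, 2, ctr, "+")
  list(outside = outside, vertices = hull@vertices, interior = interior,
       barycenters = bary)
}

#' Synthetic exponential growth series
#'
#' Area series \code{A0 * exp(r * t) * exp(N(0, sigma^2))} for direct tests
#' of the growth-fit module (no rendering involved).
#'
#' @param times numeric vector of timepoints (days).
#' @param A0 initial area.
#' @param r relative growth rate (day^-1).
#' @param sigma log-normal noise SD.
#' @return numeric vector of areas.
#' @export
makeGrowthSeries <- function(times, A0 = 100, r = 0.2, sigma = 0) {
  A0 * exp(r * times) * if (sigma > 0) exp(rnorm(length(times), 0, sigma)) else 1
}
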