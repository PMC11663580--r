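## Whole-image segmentation against a target hull, binary-mask
## post-processing, and Dice scoring.

## 4-connectivity labeling straight from EBImage; 8-connectivity obtained by
## merging 4-connected labels that touch diagonally (union-find on label
## adjacency).
.label4 <- function(mask) {
  m <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(m), nrow(mask), ncol(mask))
}

.label8 <- function(mask) {
  lab <- .label4(mask)
  nl <- max(lab)
  if (nl < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # (i, j) ~ (i+1, j+1)
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # (i+1, j) ~ (i, j+1)
  pr <- rbind(cbind(c(a1), c(b1)), cbind(c(a2), c(b2)))
  pr <- pr[pr[, 1] > 0L & pr[, 2] > 0L & pr[, 1] != pr[, 2], , drop = FALSE]
  if (!nrow(pr)) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pr))) {
    ra <- find(pr[r, 1]); rb <- find(pr[r, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  remap <- match(roots, unique(roots))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Segment a CIELAB image with a target hull
#'
#' Classifies every valid pixel as target when its colour lies inside the
#' hull or within the hull's \code{delta} (Delta E) of the hull surface.
#' Pixels excluded by the validity mask are always background.
#'
#' By default each distinct pixel colour is classified once and the verdict
#' broadcast to all pixels sharing it, which is exactly equivalent to naive
#' per-pixel classification (\code{method = "perpixel"}, kept for
#' verification) but much faster on photographs, where distinct 8-bit
#' colours are far fewer than pixels.
#'
#' @param lab a \linkS4class{LabImage}.
#' @param hull a \linkS4class{ColorHull}.
#' @param delta optional override of the hull's stored Delta E threshold.
#' @param method \code{"broadcast"} (default) or \code{"perpixel"}.
#' @return logical matrix \code{h x w}; \code{TRUE} = target.
#' @export
segmentImage <- function(lab, hull, delta = NULL,
                         method = c("broadcast", "perpixel")) {
  stopifnot(is(lab, "LabImage"), is(hull, "ColorHull"))
  method <- match.arg(method)
  d <- dim(lab@lab)
  out <- matrix(FALSE, d[1], d[2])
  v <- c(lab@valid)
  if (!any(v)) return(out)
  cols <- cbind(c(lab@lab[, , 1])[v], c(lab@lab[, , 2])[v],
                c(lab@lab[, , 3])[v])
  if (method == "perpixel") {
    verdict <- classifyColors(hull, cols, delta)
  } else {
    key <- paste(cols[, 1], cols[, 2], cols[, 3])
    first <- !duplicated(key)
    uverdict <- classifyColors(hull, cols[first, , drop = FALSE], delta)
    verdict <- uverdict[match(key, key[first])]
  }
  out[v] <- verdict
  out
}

#' Fill enclosed holes below an area threshold
#'
#' Background connected components (4-connectivity) that touch no image
#' border and cover fewer than \code{fillArea} pixels become foreground.
#' \code{fillArea = 0} is the identity.
#'
#' @param mask logical matrix; \code{TRUE} = foreground.
#' @param fillArea hole-fill threshold in pixels (>= 0).
#' @return the filled logical mask.
#' @export
fillHoles <- function(mask, fillArea = 0L) {
  stopifnot(is.logical(mask), fillArea >= 0)
  if (fillArea == 0 || all(mask)) return(mask)
  bg <- .label4(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg, nbins = max(bg))
  fill <- setdiff(which(sizes < fillArea), border)
  if (length(fill)) mask[bg %in% fill] <- TRUE
  mask
}

#' Remove small foreground objects
#'
#' Foreground connected components (8-connectivity) covering fewer than
#' \code{removeArea} pixels become background. \code{removeArea = 0} is the
#' identity.
#'
#' @param mask logical matrix; \code{TRUE} = foreground.
#' @param removeArea object-removal threshold in pixels (>= 0).
#' @return the cleaned logical mask.
#' @export
removeSmall <- function(mask, removeArea = 0L) {
  stopifnot(is.logical(mask), removeArea >= 0)
  if (removeArea == 0 || !any(mask)) return(mask)
  fg <- .label8(mask)
  sizes <- tabulate(fg, nbins = max(fg))
  drop <- which(sizes < removeArea)
  if (length(drop)) mask[fg %in% drop] <- FALSE
  mask
}

#' Post-process a segmentation mask
#'
#' Applies object removal and hole filling in that order (removing debris
#' first prevents it from sealing holes); either step is skipped at
#' threshold 0.
#'
#' @param mask logical matrix.
#' @param removeArea,fillArea pixel-count thresholds (>= 0).
#' @param order \code{"remove-fill"} (default) or \code{"fill-remove"}.
#' @return the post-processed logical mask.
#' @export
postProcessMask <- function(mask, removeArea = 0L, fillArea = 0L,
                            order = c("remove-fill", "fill-remove")) {
  order <- match.arg(order)
  if (order == "remove-fill") {
    fillHoles(removeSmall(mask, removeArea), fillArea)
  } else {
    removeSmall(fillHoles(mask, fillArea), removeArea)
  }
}

#' Dice similarity coefficient
#'
#' \code{2 |A intersect B| / (|A| + |B|)} between two binary masks; 1 is
#' perfect agreement. Two empty masks are in perfect agreement by
#' convention (1.0).
#'
#' @param a,b logical matrices of equal dimensions.
#' @return a number in [0, 1].
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' diceCoef(m, m)  # 1
#' @export
diceCoef <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1.0)
  2 * sum(a & b) / (na + nb)
}

## Boundary pixels of a mask: foreground with a 4-neighbour background (or
## image border).
.mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !core
}

#' Debug overlay with segmentation boundaries and regions of interest
#'
#' Draws the segmentation boundary over the source photograph in a
#' configurable highlight colour (magenta by default) and, when a layout is
#' supplied, each unit's region-of-interest circle in white with its integer
#' index. A pure side channel: it never alters analysis results.
#'
#' @param image sRGB array \code{h x w x 3} in [0, 1].
#' @param mask logical segmentation mask.
#' @param layout optional \linkS4class{PlateLayout}.
#' @param color boundary highlight colour (sRGB triple in [0, 1]).
#' @param dilation extra radius (pixels) for the drawn ROI circles.
#' @return sRGB array \code{h x w x 3}.
#' @export
overlayImage <- function(image, mask, layout = NULL,
                         color = c(1, 0, 1), dilation = 0) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("mask dimensions must match the image")
  out <- image
  bd <- .mask_boundary(mask)
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[bd] <- color[ch]
    out[, , ch] <- pl
  }
  if (!is.null(layout)) {
    u <- layoutUnits(layout)
    h <- dim(image)[1]; w <- dim(image)[2]
    for (k in seq_len(nrow(u))) {
      out <- .draw_circle(out, u$row[k], u$col[k], u$radius[k] + dilation)
      out <- .draw_number(out, u$unit[k],
                          max(1, round(u$row[k] - u$radius[k] - 8)),
                          min(w - 8, max(1, round(u$col[k] - 3))))
    }
  }
  out
}

.draw_circle <- function(img, r0, c0, rad, value = 1) {
  th <- seq(0, 2 * pi, length.out = max(16L, ceiling(2 * pi * rad)))
  rr <- round(r0 + rad * sin(th)); cc <- round(c0 + rad * cos(th))
  ok <- rr >= 1 & rr <= dim(img)[1] & cc >= 1 & cc <= dim(img)[2]
  for (ch in 1:3) img[cbind(rr[ok], cc[ok], ch)] <- value
  img
}

## 3 x 5 bitmap digits for ROI indices in overlays.
.DIGIT_FONT <- lapply(c(
  "111101101101111", "010110010010111", "111001111100111", "111001111001111",
  "101101111001001", "111100111001111", "111100111101111", "111001001001001",
  "111101111101111", "111101111001111"
), function(s) matrix(as.integer(strsplit(s, "")[[1]]) == 1L, 5, 3,
                      byrow = TRUE))

.draw_number <- function(img, num, r0, c0, value = 1) {
  digits <- as.integer(strsplit(as.character(num), "")[[1]])
  for (d in digits) {
    glyph <- .DIGIT_FONT[[d + 1L]]
    for (i in 1:5) for (j in 1:3) {
      if (glyph[i, j]) {
        r <- r0 + i - 1L; cc <- c0 + j - 1L
        if (r >= 1 && r <= dim(img)[1] && cc >= 1 && cc <= dim(img)[2])
          for (ch in 1:3) img[r, cc, ch] <- value
      }
    }
    c0 <- c0 + 4L
  }
  img
}
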