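## Draw bright annuli on a dark canvas (direct, independent of the fixture
## generator's renderer).
draw_rings <- function(h, w, centers, radius, value = 1, thick = 3) {
  img <- matrix(0.05, h, w)
  ri <- matrix(rep(seq_len(h), w), h, w)
  ci <- matrix(rep(seq_len(w), each = h), h, w)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((ri - centers[k, 1])^2 + (ci - centers[k, 2])^2)
    img[abs(d - radius) <= thick / 2] <- value[min(k, length(value))]
  }
  img
}

test_that("Hough transform recovers drawn circles to sub-pixel accuracy", {
  centers <- rbind(c(40, 40), c(40, 120), c(40, 200),
                   c(120, 40), c(120, 120), c(120, 200))
  img <- draw_rings(160, 240, centers, radius = 20)
  found <- detectCircles(img, 17, 23, 6)
  expect_equal(nrow(found), 6L)
  ## match each truth centre to its nearest detection (one-to-one)
  nearest <- vapply(seq_len(6), function(k) {
    d <- sqrt((found$row - centers[k, 1])^2 + (found$col - centers[k, 2])^2)
    which.min(d)
  }, integer(1))
  expect_equal(sort(nearest), 1:6)
  err <- sqrt((found$row[nearest] - centers[, 1])^2 +
                (found$col[nearest] - centers[, 2])^2)
  expect_true(all(err <= 1))
  expect_true(all(abs(found$radius - 20) <= 2))
})

test_that("detection errors report how many circles were found", {
  blank <- matrix(0.5, 80, 80)
  expect_error(detectCircles(blank, 8, 12, 3), "0 of 3")
  one <- draw_rings(100, 100, rbind(c(50, 50)), radius = 10)
  expect_error(detectCircles(one, 8, 12, 4), "1 of 4")
})

test_that("the strongest circles win when more are present than expected", {
  centers <- rbind(c(35, 35), c(35, 105), c(105, 35), c(105, 105),
                   c(35, 175), c(105, 175),   # strong
                   c(175, 35), c(175, 105))   # weak
  img <- draw_rings(210, 210, centers, radius = 14,
                    value = c(rep(1, 6), rep(0.18, 2)))
  found <- detectCircles(img, 11, 17, 6)
  ## the six strong circles are returned, the two weak ones are not
  for (k in 1:6)
    expect_true(min(sqrt((found$row - centers[k, 1])^2 +
                           (found$col - centers[k, 2])^2)) <= 1)
  for (k in 7:8)
    expect_gt(min(sqrt((found$row - centers[k, 1])^2 +
                         (found$col - centers[k, 2])^2)), 10)
})

test_that("single-linkage grouping matches the brute-force oracle", {
  ## two separable triplets
  tri <- rbind(c(0, 0), c(50, 0), c(0, 50),
               c(500, 500), c(550, 500), c(500, 550))
  colnames(tri) <- c("row", "col")
  g <- clusterCenters(tri, 100)
  expect_equal(length(unique(g)), 2L)
  expect_equal(g[1:3], rep(g[1], 3))
  expect_equal(g[4:6], rep(g[4], 3))
  ## everything within the cut -> one group
  expect_equal(length(unique(clusterCenters(tri, 1e4))), 1L)
  ## random configurations against the O(n^3) oracle
  set.seed(77)
  for (rep in 1:5) {
    xy <- cbind(row = runif(12, 0, 300), col = runif(12, 0, 300))
    cut <- runif(1, 30, 120)
    mine <- clusterCenters(xy, cut)
    ref <- oracle_single_linkage(xy, cut)
    ## same partition (labels may differ)
    expect_equal(outer(mine, mine, "=="), outer(ref, ref, "=="))
  }
})

test_that("indexing follows reading order within and across groups", {
  ## 2x2 grid, one group, row-major
  circ <- data.frame(row = c(10, 10, 60, 60), col = c(10, 60, 10, 60),
                     radius = 5)
  lay <- indexLayout(circ, ordering = "row-major")
  u <- layoutUnits(lay)
  expect_equal(u$unit[order(u$row, u$col)], c(1L, 2L, 3L, 4L))
  ## column-major swaps the traversal
  layC <- indexLayout(circ, ordering = "column-major")
  uC <- layoutUnits(layC)
  expect_equal(uC$unit[order(uC$col, uC$row)], c(1L, 2L, 3L, 4L))
  ## two vertically stacked groups of 3: group 1 gets 1-3, group 2 gets 4-6
  circ2 <- data.frame(row = c(rep(10, 3), rep(300, 3)),
                      col = rep(c(10, 60, 110), 2), radius = 5)
  lay2 <- indexLayout(circ2, groups = c(1, 1, 1, 2, 2, 2))
  u2 <- layoutUnits(lay2)
  expect_equal(u2$unit[u2$row < 100], c(1L, 2L, 3L))
  expect_equal(u2$unit[u2$row > 100], c(4L, 5L, 6L))
})

test_that("indexing tolerates row jitter and ignores input order", {
  set.seed(88)
  base <- expand.grid(row = c(20, 120, 220), col = c(20, 120, 220))
  jit <- base
  jit$row <- jit$row + sample(-3:3, 9, replace = TRUE)
  jit$col <- jit$col + sample(-3:3, 9, replace = TRUE)
  jit$radius <- 5
  base$radius <- 5
  u0 <- layoutUnits(indexLayout(base))
  u1 <- layoutUnits(indexLayout(jit))
  ## same indices at the corresponding (jittered) positions
  for (k in seq_len(9)) {
    match0 <- which(abs(u0$row - base$row[k]) < 1 & abs(u0$col - base$col[k]) < 1)
    match1 <- which(abs(u1$row - jit$row[k]) < 1 & abs(u1$col - jit$col[k]) < 1)
    expect_equal(u1$unit[match1], u0$unit[match0])
  }
  ## permuting the input rows changes nothing
  perm <- sample(nrow(jit))
  u2 <- layoutUnits(indexLayout(jit[perm, ]))
  expect_equal(u2, u1)
})

test_that("ROI rasterization labels by disc membership and nearest centre", {
  lay <- fixedLayout(data.frame(row = 30, col = 30, radius = 10))
  lab <- roiMask(lay, c(60, 60))
  expect_equal(sum(lab == 1L), pi * 100, tolerance = 0.02)
  ## non-overlapping discs keep their full areas
  lay2 <- fixedLayout(data.frame(row = c(30, 30), col = c(30, 90),
                                 radius = c(10, 10)))
  lab2 <- roiMask(lay2, c(60, 120))
  expect_equal(sum(lab2 == 1L), sum(lab2 == 2L))
  expect_false(any(attr(lab2, "overlap")))
  ## overlapping discs: contested pixels go to the nearest centre
  lay3 <- fixedLayout(data.frame(row = c(30, 30), col = c(30, 44),
                                 radius = c(10, 10)))
  lab3 <- roiMask(lay3, c(60, 74))
  u3 <- layoutUnits(lay3)
  idx <- which(lab3 > 0, arr.ind = TRUE)
  d1 <- (idx[, 1] - u3$row[1])^2 + (idx[, 2] - u3$col[1])^2
  d2 <- (idx[, 1] - u3$row[2])^2 + (idx[, 2] - u3$col[2])^2
  near <- ifelse(d1 <= d2, u3$unit[1], u3$unit[2])
  both <- d1 <= 100 & d2 <= 100
  expect_equal(lab3[lab3 > 0][both], near[both])
  expect_true(all(attr(lab3, "overlap")))
})
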