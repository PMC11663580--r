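test_that("convex hull of a tetrahedron has 4 outward facets", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h <- buildHull(tet, alpha = 0, delta = 0)
  expect_equal(nrow(hullFacets(h)), 4L)
  expect_equal(nrow(hullVertices(h)), 4L)
  expect_equal(hullVolume(h), 1 / 6, tolerance = 1e-12)
  expect_true(hullContains(h, c(0.1, 0.1, 0.1)))
  expect_false(hullContains(h, c(5, 5, 5)))
})

test_that("alpha = 0 reproduces the convex hull on random clouds", {
  set.seed(21)
  for (rep in 1:5) {
    P <- matrix(rnorm(3 * sample(8:16, 1)), ncol = 3) * 10
    h <- buildHull(P, alpha = 0)
    of <- oracle_convex_hull(P)
    expect_equal(hullVolume(h), oracle_convex_volume(P, of),
                 tolerance = 1e-9)
    Q <- matrix(rnorm(600), 200, 3) * 12
    expect_equal(hullContains(h, Q), c(oracle_convex_contains(P, of, Q)))
  }
})

test_that("alpha filtering splits distant clusters and bounds edge lengths", {
  cl1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  cl2 <- cl1 + 100
  h <- buildHull(rbind(cl1, cl2), alpha = 2, delta = 5)
  expect_equal(length(unique(hullComponents(h))), 2L)
  ## brute force over all facet edges
  f <- hullFacets(h)
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  elen <- sqrt(rowSums((hullPoints(h)[ed[, 1], ] - hullPoints(h)[ed[, 2], ])^2))
  expect_true(all(elen <= 2))
  ## union semantics: inside either component
  expect_true(hullContains(h, c(0.1, 0.1, 0.1)))
  expect_true(hullContains(h, c(100.1, 100.1, 100.1)))
  expect_false(hullContains(h, c(50, 50, 50)))
})

test_that("alpha solids grow monotonically with alpha", {
  set.seed(31)
  P <- matrix(rnorm(60), 20, 3) * 10
  Q <- matrix(rnorm(900), 300, 3) * 10
  pairs <- list(c(8, 12), c(10, 20), c(12, 40))
  for (pr in pairs) {
    h1 <- tryCatch(buildHull(P, alpha = pr[1]), error = function(e) NULL)
    h2 <- buildHull(P, alpha = pr[2])
    if (is.null(h1)) next
    in1 <- hullContains(h1, Q)
    in2 <- hullContains(h2, Q)
    expect_true(all(in2[in1]))
  }
})

test_that("containment agrees with a ray-casting oracle", {
  set.seed(41)
  for (alpha in c(0, 18)) {
    P <- matrix(rnorm(36), 12, 3) * 8
    h <- tryCatch(buildHull(P, alpha = alpha), error = function(e) NULL)
    if (is.null(h)) next
    Q <- matrix(rnorm(300), 100, 3) * 9
    mine <- hullContains(h, Q)
    ref <- vapply(seq_len(nrow(Q)), function(i) {
      oracle_raycast_contains(Q[i, ], hullPoints(h), hullFacets(h),
                              hullComponents(h))
    }, logical(1))
    expect_equal(mine, ref)
  }
})

test_that("surface distance matches the exhaustive per-facet oracle", {
  ## analytic anchors first
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 1.0
  hq <- buildHull(cube, alpha = 0)
  expect_equal(hullDistance(hq, c(2, 0.5, 0.5)), 1, tolerance = 1e-12)
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  ht <- buildHull(tet, alpha = 0)
  expect_equal(hullDistance(ht, c(0, 0, 10)), 0, tolerance = 1e-12)

  set.seed(51)
  for (alpha in c(0, 15)) {
    P <- matrix(rnorm(45), 15, 3) * 7
    h <- tryCatch(buildHull(P, alpha = alpha), error = function(e) NULL)
    if (is.null(h)) next
    Q <- matrix(rnorm(240), 80, 3) * 10
    mine <- hullDistance(h, Q)
    ref <- vapply(seq_len(nrow(Q)), function(i) {
      oracle_mesh_dist(Q[i, ], hullPoints(h), hullFacets(h))
    }, numeric(1))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("classification thresholds on distance from the hull surface", {
  tet <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  h <- buildHull(tet, alpha = 0, delta = 5)
  cloud <- makeColorCloud(h, offset = 4.9)
  expect_true(all(classifyColors(h, cloud$outside)))
  cloud2 <- makeColorCloud(h, offset = 5.1)
  expect_false(any(classifyColors(h, cloud2$outside)))
  ## inside points pass even at delta 0
  expect_true(all(classifyColors(h, cloud$interior, delta = 0)))
  ## very large (finite) delta accepts everything; infinity is rejected
  far <- matrix(rnorm(60), 20, 3) * 200
  expect_true(all(classifyColors(h, far, delta = 1e6)))
  expect_error(classifyColors(h, far, delta = Inf), "finite")
  ## facet barycenters sit exactly on the surface
  expect_equal(hullDistance(h, cloud$barycenters),
               rep(0, nrow(cloud$barycenters)), tolerance = 1e-9)
})

test_that("degenerate vertex sets raise informative errors", {
  expect_error(buildHull(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0),
               "degenerate hull")
  line <- cbind(seq(0, 5, length.out = 6), 0, 0)
  expect_error(buildHull(line, 0), "collinear|degenerate")
  plane <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(buildHull(plane, 0), "coplanar|degenerate")
  ## alpha so small that no tetrahedron survives
  set.seed(61)
  P <- matrix(rnorm(30), 10, 3) * 50
  expect_error(buildHull(P, alpha = 0.001), "empty hull at alpha")
})

test_that("hull calibration from a mask captures the foreground colours", {
  spec <- fixtureSpec(seed = 5, rows = 1, cols = 2, groups = 1,
                      nTimepoints = 1, A0 = 700, markerRadius = 24,
                      spacing = 100)
  fx <- makeImageSeries(spec)
  lab <- srgbToLab(fx$images[[1]])
  h <- hullFromMask(lab, fx$masks[[1]], minPixels = 1, alpha = 0, delta = 5,
                    binSize = 2)
  fg <- hullgrow:::.lab_pixels(lab, fx$masks[[1]])
  expect_gte(mean(hullContains(h, fg)), 0.99)
  ## error paths
  expect_error(hullFromMask(lab, matrix(FALSE, fx$dims[1], fx$dims[2])),
               "no valid pixels")
  expect_error(hullFromMask(lab, fx$masks[[1]], minPixels = 1e7),
               "min-pixels")
  expect_error(hullFromMask(lab, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("priors merge as a first-seen deduplicated union", {
  a <- rbind(c(1, 2, 3), c(4, 5, 6))
  b <- rbind(c(4, 5, 6), c(7, 8, 9))
  expect_equal(mergePriors(a, b), rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(mergePriors(NULL, b), b)
  expect_equal(mergePriors(a, NULL), a)
})

test_that("colour clouds sit at their constructed distances", {
  set.seed(71)
  P <- matrix(rnorm(30), 10, 3) * 10
  h <- buildHull(P, alpha = 0, delta = 5)
  cl <- makeColorCloud(h, offset = 0.5)
  d <- hullDistance(h, cl$outside)
  expect_equal(d, attr(cl$outside, "distance"), tolerance = 1e-9)
  expect_equal(hullDistance(h, cl$vertices), rep(0, nrow(cl$vertices)),
               tolerance = 1e-9)
  expect_true(all(hullContains(h, cl$interior)))
})
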