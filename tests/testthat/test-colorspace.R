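test_that("sRGB to CIELAB matches the stepwise textbook conversion", {
  ## achromatic anchors
  lab <- srgbToLab(array(1, dim = c(1, 1, 3)))
  expect_equal(labData(lab)[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(max(abs(labData(lab)[1, 1, 2:3])), 0.01)
  lab0 <- srgbToLab(array(0, dim = c(1, 1, 3)))
  expect_equal(c(labData(lab0)), c(0, 0, 0), tolerance = 1e-9)

  ## mid gray and a sample of random colours against the scalar oracle
  set.seed(101)
  cols <- rbind(c(118, 118, 118) / 255, matrix(runif(45), 15, 3))
  mine <- hullgrow:::.srgb_matrix_to_lab(cols)
  ref <- t(apply(cols, 1, oracle_srgb_to_lab))
  expect_lt(max(abs(mine - ref)), 1e-3)

  ## grDevices uses slightly different derived primaries; agreement is
  ## coarse but must hold
  cc <- grDevices::convertColor(cols, from = "sRGB", to = "Lab")
  expect_lt(max(abs(mine - cc)), 0.5)
})

test_that("conversion validates input shape and rescales 16-bit", {
  expect_error(srgbToLab(matrix(0, 3, 3)), "3-channel")
  expect_error(srgbToLab(array(0, dim = c(2, 2, 4))), "3-channel")
  expect_warning(lab <- srgbToLab(array(65535, dim = c(1, 1, 3))), "16-bit")
  expect_equal(labData(lab)[1, 1, 1], 100, tolerance = 1e-6)
  ## 0-255 integer input is understood
  lab8 <- srgbToLab(array(255, dim = c(1, 1, 3)))
  expect_equal(labData(lab8)[1, 1, 1], 100, tolerance = 1e-6)
})

test_that("Lab round trip recovers all 8-bit grays within one step", {
  g <- matrix(rep((0:255) / 255, 3), ncol = 3)
  back <- labToSrgb(hullgrow:::.srgb_matrix_to_lab(g))
  expect_true(all(abs(round(back * 255) - (0:255)) <= 1))
})

test_that("deltaE is the Euclidean metric on Lab", {
  expect_equal(deltaE(c(10, 2, 3), c(10, 2, 3)), 0)
  expect_equal(deltaE(c(0, 0, 0), c(0, 3, 4)), 5)
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(60), 20, 3)
  z <- matrix(rnorm(60), 20, 3)
  expect_equal(deltaE(x, y), deltaE(y, x))
  ## triangle inequality
  expect_true(all(deltaE(x, z) <= deltaE(x, y) + deltaE(y, z) + 1e-12))
})

test_that("voxelize bins by floor division and conserves counts", {
  ## uniform image -> one voxel holding every pixel
  img <- array(rep(c(0.2, 0.5, 0.3), each = 100), dim = c(10, 10, 3))
  g1 <- voxelize(srgbToLab(img), binSize = 1)
  expect_equal(nrow(voxelCenters(g1)), 1L)
  expect_equal(voxelCounts(g1), 100L)

  ## two distant colours -> two voxels, counts conserved
  img[1:5, , ] <- rep(c(0.9, 0.1, 0.1), each = 50)
  g2 <- voxelize(srgbToLab(img), binSize = 1)
  expect_equal(nrow(voxelCenters(g2)), 2L)
  expect_equal(sum(voxelCounts(g2)), 100L)

  ## random image, random bin size: counts equal the brute-force loop
  set.seed(11)
  for (bin in c(0.7, 1, 2.5)) {
    lab <- srgbToLab(random_srgb_image(13, 9, seed = bin * 100))
    g <- voxelize(lab, binSize = bin)
    m <- cbind(c(labData(lab)[, , 1]), c(labData(lab)[, , 2]),
               c(labData(lab)[, , 3]))
    ref <- oracle_bin_counts(m, bin)
    key <- apply(hullgrow:::voxelize(lab, bin)@index, 1, paste, collapse = " ")
    expect_equal(sort(as.integer(ref)), sort(voxelCounts(g)))
    expect_setequal(key, names(ref))
  }
  expect_error(voxelize(srgbToLab(img), binSize = 0), "positive")
})

test_that("voxelize respects the validity mask", {
  img <- random_srgb_image(8, 8, seed = 3)
  valid <- matrix(FALSE, 8, 8)
  valid[1:4, ] <- TRUE
  g <- voxelize(srgbToLab(img, valid = valid), binSize = 2)
  expect_equal(sum(voxelCounts(g)), 32L)
})

test_that("filterVoxels keeps bins at or above the occupancy threshold", {
  img <- array(rep(c(0.2, 0.5, 0.3), each = 100), dim = c(10, 10, 3))
  img[1:25] <- 0.9  # 25 pixels of another colour in channel-1 block
  lab <- srgbToLab(img)
  g <- voxelize(lab, binSize = 3)
  expect_gt(length(voxelCounts(g)), 1L)
  ## counts {75, 25}: the workflow value 20 keeps both, 30 keeps one
  expect_equal(length(voxelCounts(filterVoxels(g, 20))), 2L)
  expect_equal(length(voxelCounts(filterVoxels(g, 30))), 1L)
  expect_equal(filterVoxels(g, 0), g)
})
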