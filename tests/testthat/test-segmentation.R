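test_that("separable colour populations segment exactly", {
  spec <- fixtureSpec(seed = 9, rows = 1, cols = 2, groups = 1,
                      nTimepoints = 2)
  fx <- makeImageSeries(spec)
  for (i in seq_along(fx$images)) {
    lab <- srgbToLab(fx$images[[i]])
    m <- segmentImage(lab, fx$hull)
    expect_equal(diceCoef(m, fx$masks[[i]]), 1.0)
  }
})

test_that("broadcast classification equals naive per-pixel classification", {
  spec <- fixtureSpec(seed = 13, rows = 1, cols = 2, groups = 1,
                      nTimepoints = 1)
  fx <- makeImageSeries(spec)
  lab <- srgbToLab(fx$images[[1]])
  expect_identical(segmentImage(lab, fx$hull, method = "broadcast"),
                   segmentImage(lab, fx$hull, method = "perpixel"))
  ## and on an unstructured random image
  lab2 <- srgbToLab(random_srgb_image(24, 18, seed = 2))
  expect_identical(segmentImage(lab2, fx$hull, method = "broadcast"),
                   segmentImage(lab2, fx$hull, method = "perpixel"))
})

test_that("segmentation honours the validity mask and the delta limit", {
  spec <- fixtureSpec(seed = 9, rows = 1, cols = 2, groups = 1,
                      nTimepoints = 1)
  fx <- makeImageSeries(spec)
  ## empty validity mask -> all-false output
  labNone <- srgbToLab(fx$images[[1]],
                       valid = matrix(FALSE, fx$dims[1], fx$dims[2]))
  expect_false(any(segmentImage(labNone, fx$hull)))
  ## a delta covering the whole gamut -> every valid pixel is target
  lab <- srgbToLab(fx$images[[1]])
  expect_true(all(segmentImage(lab, fx$hull, delta = 1e4)))
  ## dimension mismatch is refused at construction
  expect_error(srgbToLab(fx$images[[1]], valid = matrix(TRUE, 2, 2)),
               "dimensions")
})

test_that("fillHoles fills only enclosed background below the threshold", {
  m <- matrix(FALSE, 15, 15)
  m[4:12, 4:12] <- TRUE
  m[7:9, 7:9] <- FALSE            # 9-px hole
  expect_equal(sum(fillHoles(m, 10) & !m), 9L)
  expect_identical(fillHoles(m, 9), m)    # threshold is strict
  expect_identical(fillHoles(m, 0), m)
  ## background touching the border is never filled
  open <- matrix(FALSE, 10, 10)
  open[3:8, 3:8] <- TRUE
  open[3:8, 5] <- FALSE            # slit reaching... still enclosed? no:
  open[3, 5] <- TRUE               # close the slit top; bottom still open
  open[8, 5] <- TRUE               # now enclosed
  filled <- fillHoles(open, 50)
  expect_true(all(filled[4:7, 5]))
})

test_that("removeSmall drops components below the threshold (8-connectivity)", {
  m <- matrix(FALSE, 20, 20)
  m[2:8, 2:8] <- TRUE                 # 49 px
  m[12, 12] <- TRUE; m[13, 13] <- TRUE; m[14, 14] <- TRUE  # 3 px diagonal
  out <- removeSmall(m, 10)
  expect_equal(sum(out), 49L)
  expect_identical(removeSmall(m, 0), m)
  ## diagonal chain is one 8-connected component, so it survives at 3
  expect_equal(sum(removeSmall(m, 3)), 52L)
  ## everything below the threshold -> empty
  expect_false(any(removeSmall(m, 100)))
})

test_that("post-processing is idempotent once converged", {
  spec <- fixtureSpec(seed = 17, rows = 1, cols = 2, groups = 1,
                      nTimepoints = 1, holeArea = 4, debrisArea = 4)
  fx <- makeImageSeries(spec)
  lab <- srgbToLab(fx$images[[1]])
  raw <- segmentImage(lab, fx$hull)
  p1 <- postProcessMask(raw, removeArea = 16, fillArea = 16)
  p2 <- postProcessMask(p1, removeArea = 16, fillArea = 16)
  expect_identical(p1, p2)
  expect_identical(p1, fx$masks[[1]])
})

test_that("Dice coefficient follows its closed form", {
  a <- matrix(FALSE, 10, 20); a[1:10, 1:10] <- TRUE
  expect_equal(diceCoef(a, a), 1.0)
  b <- matrix(FALSE, 10, 20); b[1:10, 11:20] <- TRUE
  expect_equal(diceCoef(a, b), 0.0)
  cc <- matrix(FALSE, 10, 20); cc[1:10, 6:15] <- TRUE  # overlap 50 of 100/100
  expect_equal(diceCoef(a, cc), 0.5)
  expect_equal(diceCoef(a, cc), diceCoef(cc, a))
  ## both empty -> perfect agreement by convention
  e <- matrix(FALSE, 5, 5)
  expect_equal(diceCoef(e, e), 1.0)
  expect_error(diceCoef(a, e), "dimensions differ")
})

test_that("overlays are a pure side channel", {
  spec <- fixtureSpec(seed = 9, rows = 1, cols = 2, groups = 1,
                      nTimepoints = 1)
  fx <- makeImageSeries(spec)
  lab <- srgbToLab(fx$images[[1]])
  m1 <- segmentImage(lab, fx$hull)
  ov <- overlayImage(fx$images[[1]], m1)
  expect_equal(dim(ov), dim(fx$images[[1]]))
  m2 <- segmentImage(lab, fx$hull)
  expect_identical(m1, m2)
  ## boundary pixels carry the highlight colour
  bd <- hullgrow:::.mask_boundary(m1)
  expect_true(all(ov[, , 1][bd] == 1 & ov[, , 2][bd] == 0 & ov[, , 3][bd] == 1))
})
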