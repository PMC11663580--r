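test_that("noiseless exponential series are recovered exactly", {
  t <- 0:5
  f <- fitRgr(t, 100 * exp(0.2 * t))
  expect_equal(f$rgr, 0.2, tolerance = 1e-12)
  expect_equal(f$intercept, log(100), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$flags, "")
  ## constant area -> zero growth
  expect_equal(fitRgr(t, rep(50, 6))$rgr, 0, tolerance = 1e-12)
})

test_that("zero areas are excluded and flagged, never imputed", {
  t <- 0:5
  a <- 100 * exp(0.2 * t)
  a[3] <- 0
  f <- fitRgr(t, a)
  expect_match(f$flags, "ZeroArea")
  expect_equal(f$n_points, 5L)
  expect_equal(f$rgr, 0.2, tolerance = 1e-12)  # remaining points are exact
  ## too few positive points -> no fit
  f2 <- fitRgr(t, c(10, rep(0, 5)))
  expect_match(f2$flags, "TooFewPoints")
  expect_true(is.na(f2$rgr))
  f3 <- fitRgr(t, rep(0, 6))
  expect_match(f3$flags, "ZeroArea")
  expect_match(f3$flags, "TooFewPoints")
})

test_that("noisy slope estimates match the OLS sampling distribution", {
  ## smaller companion to the full calibration run: 60 replicates
  set.seed(99)
  t <- 0:15
  r <- 0.2; sigma <- 0.05
  est <- replicate(60, fitRgr(t, makeGrowthSeries(t, 100, r, sigma))$rgr)
  se_theory <- sigma / sqrt(sum((t - mean(t))^2))
  expect_lt(abs(mean(est) - r), 2 * se_theory / sqrt(60) * 3)
  expect_lt(abs(sd(est) / se_theory - 1), 0.35)
})

test_that("model-fit outliers are flagged under the default thresholds", {
  set.seed(123)
  t <- 0:15
  a <- makeGrowthSeries(t, 100, 0.2, sigma = 0.15)
  base <- flagOutliers(fitRgr(t, a))
  expect_false(grepl("ModelFitOutlier", base$flags))
  ## displace one point by ten residual standard deviations
  a2 <- a
  a2[8] <- a2[8] * exp(10 * 0.15)
  out <- flagOutliers(fitRgr(t, a2))
  expect_match(out$flags, "ModelFitOutlier")
  ## sentinel thresholds disable flagging entirely
  off <- flagOutliers(fitRgr(t, a2), maxResidualStd = Inf, minRSquared = -Inf)
  expect_false(grepl("ModelFitOutlier", off$flags))
  ## the flag is advisory: the fit is retained
  expect_false(is.na(out$rgr))
})

test_that("group summaries average unflagged fits only", {
  fits <- rbind(fitRgr(0:5, 100 * exp(0.1 * (0:5)), unit = 1),
                fitRgr(0:5, 100 * exp(0.3 * (0:5)), unit = 2))
  s <- groupSummary(fits)
  expect_equal(s$groups$mean_rgr, 0.2, tolerance = 1e-12)
  expect_equal(s$groups$n, 2L)
  ## a group whose only unit is flagged reports missing with count 0
  fits$flags[1] <- "ModelFitOutlier"
  fits$flags[2] <- "ModelFitOutlier"
  s2 <- groupSummary(fits)
  expect_equal(s2$groups$n, 0L)
  expect_true(is.na(s2$groups$mean_rgr))
  ## fitted curves are the exponentiated linear fit
  s3 <- groupSummary(rbind(fitRgr(0:5, 100 * exp(0.1 * (0:5)), unit = 1)),
                     times = 0:5)
  expect_equal(s3$curves$fitted_area, 100 * exp(0.1 * (0:5)),
               tolerance = 1e-9)
})

test_that("the slope is invariant to area units and time origin", {
  t <- 2:9
  a <- 140 * exp(0.17 * t) * exp(rnorm(8, 0, 0.03))
  f1 <- fitRgr(t, a)
  scale <- 0.25
  f2 <- fitRgr(t, a * scale^2)        # calibrated units
  expect_equal(f1$rgr, f2$rgr, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, 2 * log(scale), tolerance = 1e-9)
  f3 <- fitRgr(t + 37, a)             # shifted time base
  expect_equal(f1$rgr, f3$rgr, tolerance = 1e-9)
})

test_that("area accounting matches a brute-force double loop", {
  set.seed(31)
  mask <- matrix(runif(30 * 40) > 0.6, 30, 40)
  lay <- fixedLayout(data.frame(row = c(10, 20), col = c(10, 30),
                                radius = c(8, 8)))
  labels <- roiMask(lay, c(30, 40))
  a <- areaPerUnit(mask, labels, scale = 0.5)
  ref <- integer(2)
  for (i in 1:30) for (j in 1:40) {
    if (mask[i, j] && labels[i, j] > 0)
      ref[labels[i, j]] <- ref[labels[i, j]] + 1L
  }
  expect_equal(a$area_px, ref)
  expect_equal(a$area_cal, ref * 0.25)
  ## all-false mask -> all areas zero
  expect_equal(areaPerUnit(mask & FALSE, labels)$area_px, c(0L, 0L))
  ## whole-frame fallback: one unit counting every foreground pixel
  expect_equal(areaPerUnit(mask)$area_px, sum(mask))
})
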