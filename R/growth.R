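## Per-unit area series and relative growth rate (RGR) estimation.
##
## RGR is the slope of an ordinary least-squares straight-line fit to the
## natural log of area over time, in day^-1. Quality flags:
##   ZeroArea        - records with area 0 were excluded from the fit
##   TooFewPoints    - fewer than 2 positive-area records, no fit possible
##   ModelFitOutlier - the series fits the log-linear growth model poorly

#' Per-unit foreground areas
#'
#' Counts foreground pixels inside each unit's labelled region of interest;
#' calibrated area is \code{count * scale^2}.
#'
#' @param mask logical segmentation mask.
#' @param labels integer ROI raster from \code{\link{roiMask}} (0 =
#'   unassigned). \code{NULL} treats the whole frame as unit 1.
#' @param scale physical length per pixel (e.g. mm/px); \code{NA} skips
#'   calibration.
#' @param time timestamp (days since series start) stored with each record.
#' @return data.frame with columns \code{unit}, \code{time}, \code{area_px},
#'   \code{area_cal}.
#' @export
areaPerUnit <- function(mask, labels = NULL, scale = NA_real_, time = NA_real_) {
  if (is.null(labels)) labels <- matrix(1L, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(labels)))
    stop("mask and label raster dimensions differ")
  nunit <- max(labels, 1L)
  counts <- tabulate(labels[mask], nbins = nunit)
  data.frame(unit = seq_len(nunit), time = time, area_px = counts,
             area_cal = counts * scale^2)
}

#' Fit a relative growth rate to one unit's area series
#'
#' Ordinary least squares of \code{log(area)} on time over the positive-area
#' records. Zero-area records are excluded from the fit and flagged rather
#' than substituted with a pseudo-count.
#'
#' @param time numeric vector, days since series start.
#' @param area numeric vector of areas (any consistent unit; the slope is
#'   unit-free and the intercept shifts by twice the log of the length
#'   scale).
#' @param unit unit index stored with the result.
#' @return one-row data.frame: \code{unit}, \code{rgr} (day^-1),
#'   \code{intercept} (log-area at t = 0), \code{r_squared},
#'   \code{residual_std}, \code{n_points}, \code{flags}
#'   (semicolon-separated).
#' @examples
#' t <- 0:5
#' fitRgr(t, 100 * exp(0.2 * t))$rgr  # 0.2
#' @export
fitRgr <- function(time, area, unit = 1L) {
  stopifnot(length(time) == length(area))
  flags <- character(0)
  pos <- is.finite(area) & area > 0
  if (any(!pos)) flags <- c(flags, "ZeroArea")
  if (sum(pos) < 2L) {
    flags <- c(flags, "TooFewPoints")
    return(data.frame(unit = unit, rgr = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_, residual_std = NA_real_,
                      n_points = sum(pos),
                      flags = paste(flags, collapse = ";")))
  }
  t <- time[pos]; y <- log(area[pos])
  fit <- lm(y ~ t)
  sm <- suppressWarnings(summary(fit))
  rsq <- if (stats::var(y) == 0) 1 else sm$r.squared
  ## two points interpolate exactly: no residual degrees of freedom
  sigma <- if (length(y) == 2L) 0 else sm$sigma
  if (length(y) == 2L) rsq <- 1
  data.frame(unit = unit,
             rgr = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]),
             r_squared = rsq,
             residual_std = sigma,
             n_points = sum(pos),
             flags = paste(flags, collapse = ";"))
}

#' Fit relative growth rates for every unit in an area table
#'
#' @param areas data.frame as produced by \code{\link{areaPerUnit}} rows
#'   accumulated over timepoints (columns \code{unit}, \code{time},
#'   \code{area_px} or \code{area_cal}).
#' @param useCalibrated use \code{area_cal} when available.
#' @return data.frame with one \code{\link{fitRgr}} row per unit.
#' @export
fitRgrTable <- function(areas, useCalibrated = FALSE) {
  col <- if (useCalibrated && !all(is.na(areas$area_cal))) "area_cal" else "area_px"
  units <- sort(unique(areas$unit))
  do.call(rbind, lapply(units, function(u) {
    sub <- areas[areas$unit == u, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    fitRgr(sub$time, sub[[col]], unit = u)
  }))
}

#' Flag fits that violate the log-linear growth model
#'
#' Sets the advisory \code{ModelFitOutlier} flag when the residual standard
#' deviation of log-area exceeds \code{maxResidualStd} or the coefficient of
#' determination falls below \code{minRSquared}. Flagged fits are retained;
#' the flag prompts inspection, it does not discard data. Disable either
#' criterion with \code{Inf} / \code{-Inf}.
#'
#' @param fits data.frame from \code{\link{fitRgrTable}}.
#' @param maxResidualStd residual-std ceiling (log-area units), default 0.3.
#' @param minRSquared r-squared floor, default 0.7.
#' @return the fits table with updated \code{flags}.
#' @export
flagOutliers <- function(fits, maxResidualStd = 0.3, minRSquared = 0.7) {
  bad <- !is.na(fits$rgr) & !is.na(fits$residual_std) &
    (fits$residual_std > maxResidualStd | fits$r_squared < minRSquared)
  fits$flags <- vapply(seq_len(nrow(fits)), function(i) {
    fl <- setdiff(strsplit(fits$flags[i], ";")[[1]], c("", "ModelFitOutlier"))
    if (bad[i]) fl <- c(fl, "ModelFitOutlier")
    paste(fl, collapse = ";")
  }, character(1))
  fits
}

#' Per-group growth summary and plot data
#'
#' Mean and standard deviation of RGR per group over unflagged fits (flagged
#' units are always listed, never silently dropped), plus per-unit fitted
#' curves \code{exp(intercept + rgr * t)} for plotting; flagged units are
#' marked for dashed rendering.
#'
#' @param fits data.frame from \code{\link{fitRgrTable}} /
#'   \code{\link{flagOutliers}}.
#' @param layout a \linkS4class{PlateLayout} mapping units to groups, or
#'   \code{NULL} for a single group.
#' @param times timepoints (days) at which to evaluate the fitted curves.
#' @return list with \code{groups} (columns \code{group}, \code{n},
#'   \code{mean_rgr}, \code{sd_rgr}) and \code{curves} (columns \code{unit},
#'   \code{group}, \code{time}, \code{fitted_area}, \code{dashed}).
#' @export
groupSummary <- function(fits, layout = NULL, times = NULL) {
  if (is.null(layout)) {
    grp <- setNames(rep(1L, nrow(fits)), fits$unit)
  } else {
    u <- layoutUnits(layout)
    grp <- setNames(u$group, u$unit)
  }
  fits$group <- unname(grp[as.character(fits$unit)])
  if (any(is.na(fits$group)))
    stop("fits contain units missing from the layout: ",
         paste(fits$unit[is.na(fits$group)], collapse = ", "))
  flagged <- grepl("ModelFitOutlier", fits$flags) | is.na(fits$rgr)
  groups <- do.call(rbind, lapply(sort(unique(fits$group)), function(g) {
    r <- fits$rgr[fits$group == g & !flagged]
    data.frame(group = g, n = length(r),
               mean_rgr = if (length(r)) mean(r) else NA_real_,
               sd_rgr = if (length(r) > 1) sd(r) else NA_real_)
  }))
  curves <- NULL
  if (!is.null(times)) {
    ok <- !is.na(fits$rgr)
    curves <- do.call(rbind, lapply(which(ok), function(i) {
      data.frame(unit = fits$unit[i], group = fits$group[i], time = times,
                 fitted_area = exp(fits$intercept[i] + fits$rgr[i] * times),
                 dashed = flagged[i])
    }))
  }
  list(groups = groups, curves = curves)
}
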