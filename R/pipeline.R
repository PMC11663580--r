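## Batch orchestration across an image series: Lab conversion, layout
## detection on the first frame, segmentation, post-processing, per-unit
## areas, growth fits, and reporting. Deterministic given the configuration
## and inputs; per-image processing is independent.

.log_line <- function(con, ...) {
  if (!is.null(con)) writeLines(paste0(format(Sys.time(), "%H:%M:%S "), ...),
                                con)
}

#' Segment one image with a run configuration
#'
#' @param image sRGB array \code{h x w x 3} in [0, 1].
#' @param config a \code{RunConfig}.
#' @param hull optional prebuilt \linkS4class{ColorHull} (built from the
#'   config otherwise).
#' @param valid optional validity mask.
#' @return logical segmentation mask (post-processed).
#' @export
segmentWithConfig <- function(image, config, hull = NULL, valid = NULL) {
  if (is.null(hull)) hull <- hullFromConfig(config)
  lab <- srgbToLab(image, valid = valid)
  mask <- segmentImage(lab, hull)
  postProcessMask(mask, config$segmentation$remove_area,
                  config$segmentation$fill_area)
}

#' Build the target hull described by a configuration
#'
#' Merges the configured vertices with the priors (deduplicated union,
#' selected first) and builds the hull at the configured alpha and delta.
#'
#' @param config a \code{RunConfig}.
#' @return a \linkS4class{ColorHull}.
#' @export
hullFromConfig <- function(config) {
  verts <- mergePriors(config$hull$vertices, config$hull$priors)
  if (nrow(verts) < 4L)
    stop("degenerate hull: configuration provides only ", nrow(verts),
         " vertices (need >= 4)")
  buildHull(verts, alpha = config$hull$alpha, delta = config$hull$delta)
}

.layout_from_config <- function(config, gray) {
  lc <- config$layout
  if (lc$mode == "none") return(NULL)
  if (lc$mode == "fixed") {
    um <- lc$units
    if (!is.matrix(um) || nrow(um) == 0L)
      stop("layout mode 'fixed' needs a non-empty units table")
    units <- data.frame(unit = as.integer(um[, 1]), row = um[, 2],
                        col = um[, 3], radius = um[, 4])
    units <- units[order(units$unit), , drop = FALSE]
    grp <- if (nrow(units) > 1L)
      clusterCenters(units, lc$cut_distance) else 1L
    ## canonical group numbering: by group centroid reading order
    cent <- cbind(tapply(units$row, grp, mean), tapply(units$col, grp, mean))
    ord <- order(cent[, 1], cent[, 2])
    units$group <- match(grp, as.integer(rownames(cent))[ord])
    rownames(units) <- NULL
    return(new("PlateLayout", units = units,
               cutDistance = as.numeric(lc$cut_distance),
               ordering = lc$ordering))
  }
  detectLayout(gray, lc$r_min, lc$r_max, lc$expected_n, lc$cut_distance,
               lc$ordering)
}

#' Run the full analysis over an image series
#'
#' Discovers images, parses acquisition times from filenames, detects (or
#' loads) the plate layout on the first frame and reuses it thereafter,
#' segments every frame against the configured hull, post-processes the
#' masks, aggregates per-unit areas, fits relative growth rates with
#' quality flags, and writes tidy CSV tables (and debug masks/overlays when
#' enabled) to the output directory. Unreadable images are skipped with a
#' logged warning; a layout failure aborts.
#'
#' @param config a \code{RunConfig} (see \code{\link{loadRunConfig}}).
#' @return (invisibly) list with \code{areas}, \code{fits}, \code{groups},
#'   \code{layout}, \code{files}, \code{skipped}, and output paths.
#' @export
runSeries <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  files <- Sys.glob(file.path(config$images$dir, config$images$pattern))
  if (!length(files))
    stop("no images match ", file.path(config$images$dir,
                                       config$images$pattern))
  times <- .parse_times(files, config$images$time_regex,
                        config$images$time_format)
  ord <- order(times, basename(files))
  files <- files[ord]; times <- times[ord]

  outDir <- config$output$dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file(file.path(outDir, "run.log"), open = "wt")
  on.exit(close(log), add = TRUE)
  .log_line(log, "configuration:")
  cfgTxt <- tempfile(); saveRunConfig(config, cfgTxt)
  writeLines(paste0("  ", readLines(cfgTxt)), log)

  hull <- hullFromConfig(config)
  .log_line(log, sprintf("hull: %d vertices, %d facets, alpha=%g, delta=%g",
                         nrow(hullVertices(hull)), nrow(hullFacets(hull)),
                         hull@alpha, hull@delta))

  layout <- NULL
  labels <- NULL
  scale <- config$output$scale
  if (!is.numeric(scale) || scale <= 0) scale <- NA_real_
  areas <- NULL
  skipped <- character(0)
  maskDir <- file.path(outDir, "masks")
  if (isTRUE(config$output$debug))
    dir.create(maskDir, showWarnings = FALSE)

  for (i in seq_along(files)) {
    t0 <- proc.time()[["elapsed"]]
    img <- tryCatch(readImageRaster(files[i]), error = function(e) e)
    if (inherits(img, "error")) {
      warning("skipping unreadable image ", files[i], ": ",
              conditionMessage(img))
      .log_line(log, "WARNING: skipped unreadable image ", files[i])
      skipped <- c(skipped, files[i])
      next
    }
    valid <- NULL
    if (!is.null(config$images$mask_dir)) {
      mf <- file.path(config$images$mask_dir, basename(files[i]))
      if (file.exists(mf)) valid <- readMask(mf)
    }
    if (is.null(layout) && config$layout$mode != "none") {
      layout <- .layout_from_config(config, luminance(img))
      .log_line(log, sprintf("layout: %d units in %d groups",
                             nrow(layoutUnits(layout)),
                             length(unique(layoutUnits(layout)$group))))
    }
    if (is.null(labels)) {
      labels <- if (is.null(layout)) NULL else
        roiMask(layout, dim(img)[1:2], config$layout$dilation)
    }
    lab <- srgbToLab(img, valid = valid)
    mask <- segmentImage(lab, hull)
    mask <- postProcessMask(mask, config$segmentation$remove_area,
                            config$segmentation$fill_area)
    a <- areaPerUnit(mask, labels, scale = scale, time = times[i])
    a$image <- basename(files[i])
    areas <- rbind(areas, a)
    if (isTRUE(config$output$debug)) {
      stem <- tools::file_path_sans_ext(basename(files[i]))
      writeMask(mask, file.path(maskDir, paste0(stem, "_mask.png")))
      ov <- overlayImage(img, mask, layout,
                         color = config$output$overlay_color,
                         dilation = config$layout$dilation)
      writeImageRaster(ov, file.path(maskDir, paste0(stem, "_overlay.png")))
    }
    .log_line(log, sprintf("%s: %d target px, %.2f s", basename(files[i]),
                           sum(mask), proc.time()[["elapsed"]] - t0))
  }
  if (is.null(areas)) stop("no readable images in the series")

  gcol <- if (is.null(layout)) NULL else
    setNames(layoutUnits(layout)$group, layoutUnits(layout)$unit)
  areas$group <- if (is.null(gcol)) 1L else unname(gcol[as.character(areas$unit)])
  areas <- areas[, c("image", "unit", "group", "time", "area_px", "area_cal")]

  fits <- fitRgrTable(areas)
  fits <- flagOutliers(fits, config$growth$max_residual_std,
                       config$growth$min_r_squared)
  summ <- groupSummary(fits, layout, times = sort(unique(areas$time)))

  areasCsv <- file.path(outDir, "areas.csv")
  fitsCsv <- file.path(outDir, "fits.csv")
  groupsCsv <- file.path(outDir, "groups.csv")
  write.csv(areas, areasCsv, row.names = FALSE)
  write.csv(fits, fitsCsv, row.names = FALSE)
  write.csv(summ$groups, groupsCsv, row.names = FALSE)
  .log_line(log, "wrote ", areasCsv, ", ", fitsCsv, ", ", groupsCsv)

  invisible(list(areas = areas, fits = fits, groups = summ$groups,
                 curves = summ$curves, layout = layout, files = files,
                 skipped = skipped,
                 paths = c(areas = areasCsv, fits = fitsCsv,
                           groups = groupsCsv)))
}

#' Compare predicted masks against reference masks
#'
#' Pairs files by name between two directories and reports the Dice
#' similarity coefficient per pair plus the mean and standard deviation
#' (reported in \code{mean +/- SD} style). Unmatched files are listed;
#' a dimension mismatch is recorded as a failure and the run continues.
#'
#' @param predDir directory of predicted masks.
#' @param refDir directory of reference masks (same filenames).
#' @param pattern filename glob for both directories.
#' @return list with \code{table} (file, dice), \code{mean}, \code{sd},
#'   \code{unmatched}, \code{failures}.
#' @export
evaluateMasks <- function(predDir, refDir, pattern = "*.png") {
  pf <- basename(Sys.glob(file.path(predDir, pattern)))
  rf <- basename(Sys.glob(file.path(refDir, pattern)))
  common <- intersect(pf, rf)
  unmatched <- c(setdiff(pf, rf), setdiff(rf, pf))
  if (!length(common)) stop("no matching filenames between ", predDir,
                            " and ", refDir)
  res <- data.frame(file = common, dice = NA_real_)
  failures <- character(0)
  for (i in seq_along(common)) {
    p <- readMask(file.path(predDir, common[i]))
    r <- readMask(file.path(refDir, common[i]))
    d <- tryCatch(diceCoef(p, r), error = function(e) e)
    if (inherits(d, "error")) {
      failures <- c(failures, paste0(common[i], ": ", conditionMessage(d)))
    } else res$dice[i] <- d
  }
  ok <- !is.na(res$dice)
  out <- list(table = res, mean = mean(res$dice[ok]),
              sd = if (sum(ok) > 1) sd(res$dice[ok]) else NA_real_,
              unmatched = unmatched, failures = failures)
  class(out) <- "maskEvaluation"
  out
}

#' @export
print.maskEvaluation <- function(x, ...) {
  cat(sprintf("Dice over %d mask pair(s): %.3f +/- %.3f (mean +/- SD)\n",
              sum(!is.na(x$table$dice)), x$mean, x$sd))
  worst <- x$table[which.min(x$table$dice), ]
  if (nrow(worst)) cat(sprintf("minimum: %.3f (%s)\n", worst$dice, worst$file))
  if (length(x$unmatched))
    cat("unmatched files:", paste(x$unmatched, collapse = ", "), "\n")
  if (length(x$failures))
    cat("failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' Write a fixture series to disk as a ready-to-run demo dataset
#'
#' Saves the rendered frames as \code{t<k>.png}, the truth masks under
#' \code{truth/}, and a matching run configuration, so the whole pipeline
#' can be exercised from files alone.
#'
#' @param fx result of \code{\link{makeImageSeries}}.
#' @param dir output directory (created if needed).
#' @param spec the \code{\link{fixtureSpec}} used (for config parameters).
#' @return the configuration file path.
#' @export
writeFixtureSeries <- function(fx, dir, spec) {
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fx$images)) {
    fn <- sprintf("t%d.png", i - 1L)
    writeImageRaster(fx$images[[i]], file.path(dir, fn))
    writeMask(fx$masks[[i]], file.path(dir, "truth", fn))
  }
  cfg <- defaultRunConfig()
  cfg$images$dir <- dir
  cfg$images$pattern <- "t*.png"
  cfg$hull$vertices <- spec$hullVertices
  cfg$hull$delta <- spec$delta
  cfg$segmentation$fill_area <- if (spec$holeArea > 0) 4 * spec$holeArea else 0
  cfg$segmentation$remove_area <- if (spec$debrisArea > 0)
    4 * spec$debrisArea else 0
  cfg$layout$mode <- "detect"
  cfg$layout$r_min <- spec$markerRadius - 3
  cfg$layout$r_max <- spec$markerRadius + 3
  cfg$layout$expected_n <- nrow(fx$layout)
  cfg$layout$cut_distance <- 1.5 * spec$spacing
  cfg$output$dir <- file.path(dir, "out")
  path <- file.path(dir, "config.txt")
  saveRunConfig(cfg, path)
  path
}
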