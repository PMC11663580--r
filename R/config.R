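## Run configuration: a small human-readable key/value text format with
## [section] headers, chosen for diff-ability and bit-exact decimal
## round-tripping (doubles are written with 17 significant digits, which
## as.numeric() inverts exactly).

.fmt_value <- function(v) {
  if (is.character(v)) return(paste0('"', v, '"'))
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.matrix(v)) {
    rows <- apply(v, 1, function(r)
      paste0("[", paste(sprintf("%.17g", r), collapse = ", "), "]"))
    return(paste0("[", paste(rows, collapse = ", "), "]"))
  }
  if (length(v) > 1L)
    return(paste0("[", paste(sprintf("%.17g", v), collapse = ", "), "]"))
  sprintf("%.17g", v)
}

## Recursive-descent parser for bracketed numeric lists. Returns either a
## numeric vector or a list of numeric vectors, plus the index just past the
## parsed region.
.parse_list <- function(s, pos, where) {
  skip <- function(p) { while (p <= nchar(s) && substr(s, p, p) == " ") p <- p + 1L; p }
  pos <- skip(pos)
  if (substr(s, pos, pos) != "[")
    stop(where, ": expected '[' in list value")
  pos <- pos + 1L
  items <- list()
  repeat {
    pos <- skip(pos)
    ch <- substr(s, pos, pos)
    if (ch == "]") { pos <- pos + 1L; break }
    if (ch == ",") { pos <- pos + 1L; next }
    if (ch == "[") {
      sub <- .parse_list(s, pos, where)
      items[[length(items) + 1L]] <- sub$value
      pos <- sub$pos
    } else {
      m <- regexpr("^[-+0-9.eE]+", substr(s, pos, nchar(s)))
      if (m == -1L) stop(where, ": malformed number at '",
                         substr(s, pos, min(nchar(s), pos + 10)), "'")
      tok <- regmatches(substr(s, pos, nchar(s)), m)
      val <- suppressWarnings(as.numeric(tok))
      if (is.na(val)) stop(where, ": malformed number '", tok, "'")
      items[[length(items) + 1L]] <- val
      pos <- pos + attr(m, "match.length")
    }
    if (pos > nchar(s)) stop(where, ": unterminated list")
  }
  if (all(vapply(items, function(x) is.numeric(x) && length(x) == 1L,
                 logical(1)))) {
    list(value = as.numeric(unlist(items)), pos = pos)
  } else {
    list(value = items, pos = pos)
  }
}

.parse_value <- function(s, where) {
  s <- trimws(s)
  if (s == "true") return(TRUE)
  if (s == "false") return(FALSE)
  if (startsWith(s, '"')) {
    if (!endsWith(s, '"')) stop(where, ": unterminated string")
    return(substr(s, 2L, nchar(s) - 1L))
  }
  if (startsWith(s, "[")) {
    out <- .parse_list(s, 1L, where)
    v <- out$value
    if (is.list(v)) {
      if (any(vapply(v, length, integer(1)) !=
              length(v[[1]])))
        stop(where, ": ragged nested list (each row needs the same length)")
      return(do.call(rbind, v))
    }
    return(v)
  }
  val <- suppressWarnings(as.numeric(s))
  if (is.na(val)) stop(where, ": cannot parse value '", s, "'")
  val
}

#' Default run configuration
#'
#' The full configuration template for \code{\link{runSeries}}: image
#' discovery and timestamp parsing, hull specification (vertices, alpha,
#' delta, priors), segmentation post-processing, layout detection, and
#' output options. See the package vignette for the meaning and units of
#' every key.
#'
#' @return a named list of sections, class \code{RunConfig}.
#' @export
defaultRunConfig <- function() {
  cfg <- list(
    images = list(dir = ".", pattern = "*.png",
                  time_regex = "t([0-9]+)", time_format = "number"),
    hull = list(alpha = 0, delta = 5,
                vertices = matrix(numeric(0), 0, 3),
                priors = matrix(numeric(0), 0, 3)),
    segmentation = list(bin_size = 1, min_pixels = 20,
                        fill_area = 0, remove_area = 0),
    layout = list(mode = "none", r_min = 10, r_max = 20, expected_n = 1,
                  cut_distance = 100, ordering = "row-major", dilation = 3,
                  units = matrix(numeric(0), 0, 4)),
    growth = list(max_residual_std = 0.3, min_r_squared = 0.7),
    output = list(dir = "out", scale = 0, debug = FALSE,
                  overlay_color = c(1, 0, 1))
  )
  class(cfg) <- "RunConfig"
  cfg
}

.REQUIRED_KEYS <- list(images = c("dir", "pattern"),
                       hull = c("alpha", "delta", "vertices"),
                       segmentation = c("fill_area", "remove_area"),
                       layout = "mode",
                       output = "dir")

#' Save a run configuration
#'
#' Writes the configuration as diff-friendly text; decimal fields round-trip
#' bit-exactly through \code{\link{loadRunConfig}}.
#'
#' @param config a \code{RunConfig} list.
#' @param path output file path.
#' @export
saveRunConfig <- function(config, path) {
  lines <- character(0)
  for (sec in names(config)) {
    lines <- c(lines, paste0("[", sec, "]"))
    for (key in names(config[[sec]])) {
      lines <- c(lines, paste0(key, " = ", .fmt_value(config[[sec]][[key]])))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a run configuration
#'
#' Parses a configuration file, checks that every required key is present
#' (all missing keys are named in one error), and applies any overrides
#' (e.g. from command-line flags) on top of the file values. Vertex rows
#' must be Lab triples; a malformed row is reported with its line number.
#'
#' @param path configuration file path.
#' @param overrides named list of \code{section$key} values that take
#'   precedence over the file (e.g. \code{list(hull = list(delta = 5))}).
#' @return a \code{RunConfig} list.
#' @export
loadRunConfig <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- readLines(path)
  cfg <- list()
  sec <- NULL
  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (line == "" || startsWith(line, "#")) next
    where <- paste0(basename(path), ":", i)
    if (grepl("^\\[.*\\]$", line)) {
      sec <- gsub("^\\[|\\]$", "", line)
      if (is.null(cfg[[sec]])) cfg[[sec]] <- list()
      next
    }
    if (is.null(sec)) stop(where, ": key before any [section] header")
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq == -1L) stop(where, ": expected 'key = value'")
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- .parse_value(substr(line, eq + 1L, nchar(line)), where)
    if (key %in% c("vertices", "priors")) {
      if (is.numeric(val) && !is.matrix(val) && length(val) == 0) {
        val <- matrix(numeric(0), 0, 3)
      } else {
        if (!is.matrix(val) && length(val) == 3L) val <- matrix(val, 1, 3)
        if (!is.matrix(val) || ncol(val) != 3L)
          stop(where, ": '", key, "' rows must be L,a,b triples")
      }
    }
    if (key == "units" && is.numeric(val) && !is.matrix(val) &&
        length(val) == 0)
      val <- matrix(numeric(0), 0, 4)
    cfg[[sec]][[key]] <- val
  }
  missing <- character(0)
  for (sec in names(.REQUIRED_KEYS)) {
    for (key in .REQUIRED_KEYS[[sec]]) {
      if (is.null(cfg[[sec]][[key]]))
        missing <- c(missing, paste0(sec, ".", key))
    }
  }
  if (length(missing))
    stop("configuration is missing required keys: ",
         paste(missing, collapse = ", "))
  ## fill unspecified optional keys with defaults
  def <- defaultRunConfig()
  for (sec in names(def)) {
    for (key in names(def[[sec]])) {
      if (is.null(cfg[[sec]][[key]])) cfg[[sec]][[key]] <- def[[sec]][[key]]
    }
  }
  if (!is.null(overrides)) {
    for (sec in names(overrides)) {
      for (key in names(overrides[[sec]])) {
        cfg[[sec]][[key]] <- overrides[[sec]][[key]]
      }
    }
  }
  class(cfg) <- "RunConfig"
  cfg
}

## Parse acquisition times (in days since the first image) from filenames.
## time_format "number": the first capture group is already a numeric time
## in days; otherwise it is a strptime format applied to the capture.
.parse_times <- function(files, time_regex, time_format) {
  m <- regmatches(basename(files), regexec(time_regex, basename(files)))
  tok <- vapply(m, function(x) if (length(x) >= 2L) x[2] else NA_character_,
                character(1))
  if (anyNA(tok))
    stop("timestamp pattern '", time_regex, "' does not match: ",
         paste(basename(files)[is.na(tok)], collapse = ", "))
  if (identical(time_format, "number")) {
    tt <- as.numeric(tok)
  } else {
    tt <- as.numeric(difftime(strptime(tok, time_format, tz = "UTC"),
                              strptime(tok[1], time_format, tz = "UTC"),
                              units = "days"))
  }
  tt - min(tt)
}
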