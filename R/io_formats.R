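#' Read a tabular eye-tracking export
#'
#' Reads a CSV or TSV export from a video-based eye tracker into a validated
#' table. The delimiter (comma or tab) is auto-detected. Device units are
#' preserved untouched; missing or invalid samples become `NaN` with
#' `validity_* = FALSE`. The sampling rate is inferred from the median
#' timestamp spacing unless supplied.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named character vector mapping canonical names
#'   (`time`, `pupil_left`, `pupil_right`, `gaze_x`, `gaze_y`,
#'   `validity_left`, `validity_right`) to the file's column names. `time`
#'   and at least one pupil column are required; validity columns are
#'   optional (derived from missingness when absent).
#' @param fs Sampling rate in Hz; inferred from timestamps when `NULL`.
#' @param unit Free-text device unit carried as metadata (default `"a.u."`).
#' @return An object of class `eyetrack_table`: a data frame with canonical
#'   columns and attributes `fs` and `unit`.
#' @export
read_eyetrack <- function(path, column_map, fs = NULL, unit = "a.u.") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("eye-tracking file not found: ", path)
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "NaN", ""))
  canonical <- c("time", "pupil_left", "pupil_right", "gaze_x", "gaze_y",
                 "validity_left", "validity_right")
  extra <- setdiff(names(column_map), canonical)
  if (length(extra)) stop("unknown canonical names in column_map: ",
                          paste(extra, collapse = ", "))
  needed <- intersect(canonical, names(column_map))
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols))
    stop("format error: mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  if (!"time" %in% needed) stop("column_map must map 'time'")
  if (!any(c("pupil_left", "pupil_right") %in% needed))
    stop("column_map must map at least one pupil column")

  out <- data.frame(time = as.numeric(raw[[column_map[["time"]]]]))
  if (any(!is.finite(out$time))) stop("format error: non-finite timestamps")
  if (is.unsorted(out$time)) stop("format error: non-monotone time column")
  for (nm in c("pupil_left", "pupil_right", "gaze_x", "gaze_y")) {
    out[[nm]] <- if (nm %in% needed)
      as.numeric(raw[[column_map[[nm]]]]) else NA_real_
  }
  for (side in c("left", "right")) {
    vcol <- paste0("validity_", side)
    pcol <- paste0("pupil_", side)
    v <- if (vcol %in% needed) parse_validity(raw[[column_map[[vcol]]]])
         else rep(TRUE, nrow(out))
    v <- v & is.finite(out[[pcol]])
    out[[pcol]][!v] <- NaN
    out[[vcol]] <- v
  }
  if (is.null(fs)) {
    dt <- diff(out$time)
    dt <- dt[dt > 0]
    if (!length(dt)) stop("cannot infer sampling rate from timestamps")
    fs <- 1 / stats::median(dt)
  }
  stopifnot(fs > 0)
  structure(out, fs = fs, unit = unit, class = c("eyetrack_table", "data.frame"))
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

parse_validity <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "valid", "yes")
}

#' Construct a frame stack
#'
#' @param frames `T x H x W x 3` array of 8-bit intensities in `[0, 255]`.
#' @param fs Frame rate in Hz (default 12, the snapshot rate of the
#'   screen-capture pipeline).
#' @param timestamps Frame times in seconds; defaults to `(0:(T-1))/fs`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fs = 12, timestamps = NULL) {
  d <- dim(frames)
  if (length(d) != 4L || d[4] != 3L)
    stop("frames must be a T x H x W x 3 array")
  if (d[2] < 1L || d[3] < 1L) stop("frame height/width must be positive")
  if (is.null(timestamps)) timestamps <- (seq_len(d[1]) - 1) / fs
  if (length(timestamps) != d[1]) stop("timestamps length must match frames")
  if (d[1] > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = timestamps, fs = fs),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %.3g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Read a directory of PNG frames
#'
#' Frames are read in lexicographic filename order, which must equal temporal
#' order. With `stride = s`, frames at 0-based indices `0, s, 2s, ...` are
#' kept (the screen-capture analysis keeps every 10th rendered frame to reach
#' 12 Hz). Video files are not supported in this build; supply PNG
#' directories.
#'
#' @param path Directory containing `.png` files.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @param fs Frame rate of the *kept* frames, in Hz (default 12).
#' @return A [frame_stack()] with 8-bit intensities in `[0, 255]`.
#' @export
read_frames <- function(path, stride = 1L, fs = 12) {
  stopifnot(length(path) == 1L, stride >= 1L)
  if (!file.exists(path)) stop("frame source not found: ", path)
  if (!dir.exists(path)) {
    if (grepl("\\.(mp4|avi|mov|mkv)$", tolower(path)))
      stop("video decoding is not available in this build; ",
           "extract frames to a PNG directory instead")
    stop("frame source must be a directory of PNG files: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("empty frame source: no PNG files in ", path)
  keep <- files[seq(1L, length(files), by = as.integer(stride))]
  imgs <- lapply(keep, read_png_rgb)
  dims <- vapply(imgs, dim, integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: mixed frame sizes in ", path)
  a <- array(0, c(length(imgs), dims[1, 1], dims[2, 1], 3L))
  for (t in seq_along(imgs)) a[t, , , ] <- imgs[[t]]
  frame_stack(a, fs = fs)
}

# Read one PNG as an H x W x 3 array of 8-bit values.
read_png_rgb <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write a bundle of 2-D maps as CSV matrices with JSON sidecars
#'
#' Each 2-D map (or each channel slice of a 3-D map) is written as a plain
#' CSV matrix `<name>.csv` plus `<name>.json` describing the statistic,
#' channel, degrees of freedom, FDR level and provenance. Values are written
#' with full double precision so a round-trip read reproduces them exactly.
#'
#' @param result Named list of numeric matrices and/or 3-D arrays
#'   (`rows x cols x channels`), or a single matrix.
#' @param path Output directory (created if needed).
#' @param meta Named list merged into every sidecar (e.g. `statistic`, `df`,
#'   `q`).
#' @return Invisibly, the character vector of files written.
#' @export
write_map_bundle <- function(result, path, meta = list()) {
  if (is.matrix(result)) result <- list(map = result)
  if (!length(result)) stop("empty map bundle")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("I/O error: cannot create ", path)
  written <- character(0)
  for (nm in names(result)) {
    x <- result[[nm]]
    if (is.null(dim(x)) || !is.numeric(x)) stop("map '", nm, "' is not numeric")
    slices <- if (length(dim(x)) == 3L)
      setNames(lapply(seq_len(dim(x)[3]), function(k) x[, , k]),
               paste0(nm, "_ch", seq_len(dim(x)[3])))
    else setNames(list(x), nm)
    for (snm in names(slices)) {
      m <- slices[[snm]]
      if (!length(m)) stop("empty map: ", snm)
      csv <- file.path(path, paste0(snm, ".csv"))
      utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                         csv, sep = ",", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      side <- c(list(name = snm, nrow = nrow(m), ncol = ncol(m)), meta)
      jsonlite::write_json(side, file.path(path, paste0(snm, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      written <- c(written, csv, file.path(path, paste0(snm, ".json")))
    }
  }
  invisible(written)
}

#' Read back one map written by [write_map_bundle()]
#'
#' @param path Directory of the bundle.
#' @param name Map name (file stem).
#' @return List with `map` (numeric matrix) and `meta` (sidecar list).
#' @export
read_map_bundle <- function(path, name) {
  csv <- file.path(path, paste0(name, ".csv"))
  if (!file.exists(csv)) stop("no such map in bundle: ", name)
  m <- as.matrix(utils::read.table(csv, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(file.path(path, paste0(name, ".json")),
                              simplifyVector = TRUE)
  list(map = m, meta = meta)
}

#' Load and validate a JSON run configuration
#'
#' Unknown keys are rejected so that typos in config files fail loudly.
#' Numeric fields are checked against documented bounds.
#'
#' @param path Path to a JSON file, or a named list already in memory.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(
    lag_ms = 500, window_half = 350L, downsample_factor = 10L,
    fdr_q = 0.01, channel_space = "rgb_lum", target_fs = 12,
    k1 = 2.0, k2 = 2.5, blink_pad_ms = 50, hann_ms = 11,
    blink_min_ms = 50, blink_max_ms = 500,
    gamma = c(2.24, 2.23, 2.22), seed = 1L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$lag_ms >= 0, cfg$lag_ms <= 5000,
            cfg$window_half >= 1, cfg$downsample_factor >= 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$channel_space %in% c("rgb_lum", "cielab"),
            cfg$target_fs > 0, cfg$k2 > cfg$k1, cfg$k1 > 0,
            all(cfg$gamma > 0), length(cfg$gamma) == 3L)
  structure(cfg, class = c("run_config", "list"))
}
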