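# File formats: CSV interchange for markers, sensors and angles; read-only
# TRC import for marker trajectories; stream alignment.

check_uniform_time <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) && (max(dt) - min(dt) > tol || any(dt <= 0))) {
    bad <- which(abs(dt - stats::median(dt)) > tol)[1] + 1L
    lum_error(sprintf("non-uniform time axis near row %d", bad),
              class = "lum_schema_error", row = bad)
  }
  invisible(time_s)
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    lum_error(sprintf("%s file not found: %s", what, path),
              class = "lum_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    lum_error(sprintf("%s file %s missing columns: %s", what, basename(path),
                      paste(missing, collapse = ", ")),
              class = "lum_schema_error", columns = missing)
  }
  if (anyNA(df[required])) {
    bad <- which(rowSums(is.na(df[required])) > 0)[1]
    lum_error(sprintf("%s file %s has NaN/NA at row %d", what,
                      basename(path), bad),
              class = "lum_schema_error", row = bad)
  }
  check_uniform_time(df$time_s)
  df
}

#' Read and write marker, sensor and angle CSV files
#'
#' Canonical CSV schemas: markers have `time_s` plus `<MARKER>_x/_y/_z`
#' columns (mm) for the ten landmarks; sensors have `time_s`,
#' `dl1_mm` ... `dl4_mm`; angles have `time_s`, `fx_deg`, `sb_deg`,
#' `rt_deg`. Values are written with full precision, so a write-then-read
#' round trip reproduces them to better than 1e-9.
#'
#' @param path File path.
#' @return The parsed data frame (readers) or `invisible(path)` (writers).
#' @export
read_markers <- function(path) {
  cols <- c("time_s", as.vector(t(outer(MARKER_NAMES, c("_x", "_y", "_z"),
                                        paste0))))
  read_table_checked(path, cols, "marker")
}

#' @rdname read_markers
#' @export
read_sensors <- function(path) {
  read_table_checked(path, c("time_s", SENSOR_COLS), "sensor")
}

#' @rdname read_markers
#' @export
read_angles <- function(path) {
  df <- read_table_checked(path, c("time_s", AXES), "angle")
  new_angle_series(df$time_s, df$fx_deg, df$sb_deg, df$rt_deg)
}

write_full_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_markers
#' @param x Data frame to write.
#' @export
write_markers <- function(x, path) {
  check_marker_frame(x)
  write_full_csv(x, path)
}

#' @rdname read_markers
#' @export
write_sensors <- function(x, path) {
  check_sensor_recording(x)
  write_full_csv(x, path)
}

#' @rdname read_markers
#' @export
write_angles <- function(x, path) {
  check_angle_series(x)
  write_full_csv(as.data.frame(x)[c("time_s", AXES)], path)
}

#' Read marker trajectories from a TRC file
#'
#' Parses the standard TRC layout (PathFileType line, header-field rows,
#' marker-name row, X/Y/Z label row, data block). Marker names are matched
#' case-insensitively against the canonical ten-landmark set; `aliases` maps
#' additional file-side names to canonical names. Units of `m` are converted
#' to mm.
#'
#' @param path TRC file path.
#' @param aliases Named character vector: `c(file_name = "CANONICAL")`.
#' @return Marker trajectory data frame (`time_s` + `<MARKER>_x/_y/_z`).
#' @export
read_trc <- function(path, aliases = NULL) {
  if (!file.exists(path)) {
    lum_error(sprintf("TRC file not found: %s", path), class = "lum_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1])) {
    lum_error("not a TRC file (missing PathFileType header)",
              class = "lum_schema_error")
  }
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(vals[seq_along(keys)]), keys)
  rate <- as.numeric(hdr[["DataRate"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  units <- if (!is.null(hdr[["Units"]])) hdr[["Units"]] else "mm"
  name_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  canon <- function(nm) {
    nm0 <- trimws(nm)
    if (!is.null(aliases) && tolower(nm0) %in% tolower(names(aliases))) {
      return(aliases[[which(tolower(names(aliases)) == tolower(nm0))[1]]])
    }
    hit <- MARKER_NAMES[tolower(MARKER_NAMES) == tolower(nm0)]
    if (length(hit)) hit[1] else NA_character_
  }
  mapped <- vapply(marker_names, canon, character(1))
  if (anyNA(mapped)) {
    lum_error(sprintf("unrecognized TRC marker name(s): %s",
                      paste(marker_names[is.na(mapped)], collapse = ", ")),
              class = "lum_schema_error")
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(strsplit(data_lines, "\t"), as.numeric)
  ncol_expected <- 2 + 3 * length(mapped)
  mat <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncol_expected)]))
  if (nrow(mat) != n_frames) {
    lum_error(sprintf("TRC header declares %d frames but file has %d",
                      n_frames, nrow(mat)), class = "lum_schema_error")
  }
  scale <- if (tolower(units) == "m") 1000 else 1
  out <- data.frame(time_s = mat[, 2])
  for (j in seq_along(mapped)) {
    base <- 2 + 3 * (j - 1)
    out[[paste0(mapped[j], "_x")]] <- mat[, base + 1] * scale
    out[[paste0(mapped[j], "_y")]] <- mat[, base + 2] * scale
    out[[paste0(mapped[j], "_z")]] <- mat[, base + 3] * scale
  }
  missing <- setdiff(MARKER_NAMES, mapped)
  if (length(missing)) {
    lum_error(sprintf("TRC file lacks landmarks: %s",
                      paste(missing, collapse = ", ")),
              class = "lum_schema_error", columns = missing)
  }
  if (is.finite(rate) && rate > 0) {
    check_uniform_time(out$time_s)
  }
  out
}

#' Align marker and sensor streams on a common time axis
#'
#' Both streams must share the nominal sampling rate (the acquisition is
#' co-triggered); they are cropped to the overlapping time range and a
#' residual sample-count mismatch of at most one is resolved by truncating
#' the longer stream.
#'
#' @param markers Marker data frame.
#' @param sensors Sensor data frame.
#' @param fs_tol Relative tolerance on the sampling-rate match.
#' @return List with aligned `markers` and `sensors`.
#' @export
align_streams <- function(markers, sensors, fs_tol = 1e-6) {
  fs_m <- series_fs(markers$time_s)
  fs_s <- series_fs(sensors$time_s)
  if (abs(fs_m - fs_s) > fs_tol * fs_m) {
    lum_error(sprintf("sampling rates differ (%g vs %g Hz); no resampling is done",
                      fs_m, fs_s), class = "lum_alignment_error")
  }
  t0 <- max(min(markers$time_s), min(sensors$time_s))
  t1 <- min(max(markers$time_s), max(sensors$time_s))
  if (t1 <= t0) {
    lum_error("marker and sensor time ranges do not overlap",
              class = "lum_alignment_error")
  }
  eps <- 0.5 / fs_m
  m <- markers[markers$time_s >= t0 - eps & markers$time_s <= t1 + eps, ]
  s <- sensors[sensors$time_s >= t0 - eps & sensors$time_s <= t1 + eps, ]
  if (abs(nrow(m) - nrow(s)) > 1) {
    lum_error(sprintf("streams differ by %d samples after cropping",
                      abs(nrow(m) - nrow(s))), class = "lum_alignment_error")
  }
  n <- min(nrow(m), nrow(s))
  list(markers = m[seq_len(n), , drop = FALSE],
       sensors = s[seq_len(n), , drop = FALSE])
}
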