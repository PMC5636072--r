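# The stretch-sensor angle estimator: crosstalk adjustment of the oblique
# channels, the three scalar features, short-window linear calibration and
# angle reconstruction.

SENSOR_COLS <- c("dl1_mm", "dl2_mm", "dl3_mm", "dl4_mm")

check_sensor_recording <- function(rec) {
  missing <- setdiff(c("time_s", SENSOR_COLS), names(rec))
  if (length(missing)) {
    lum_error(sprintf("sensor data missing columns: %s",
                      paste(missing, collapse = ", ")),
              class = "lum_schema_error", columns = missing)
  }
  if (anyNA(rec[SENSOR_COLS])) {
    bad <- which(rowSums(is.na(rec[SENSOR_COLS])) > 0)[1]
    lum_error(sprintf("NaN/NA sensor data at row %d", bad),
              class = "lum_schema_error", row = bad)
  }
  invisible(rec)
}

#' Crosstalk adjustment of the oblique channels
#'
#' Subtracts vertical-channel displacement from the oblique channels to
#' remove the flexion/side-bending loading the obliques share with the
#' verticals: with ipsilateral pairing (the default, geometrically nearest)
#' `dl3' = dl3 - dl1` and `dl4' = dl4 - dl2`.
#'
#' @param recording Sensor recording (`time_s`, `dl1_mm` ... `dl4_mm`).
#' @param pairing `"ipsilateral"`, `"contralateral"`, or `"mean"` (subtract
#'   the mean of the two verticals from each oblique).
#' @return Data frame with `dl3_adj_mm`, `dl4_adj_mm`.
#' @export
adjust_oblique <- function(recording,
                           pairing = c("ipsilateral", "contralateral", "mean")) {
  pairing <- match.arg(pairing)
  check_sensor_recording(recording)
  v <- switch(pairing,
    ipsilateral = cbind(recording$dl1_mm, recording$dl2_mm),
    contralateral = cbind(recording$dl2_mm, recording$dl1_mm),
    mean = {
      m <- (recording$dl1_mm + recording$dl2_mm) / 2
      cbind(m, m)
    })
  data.frame(dl3_adj_mm = recording$dl3_mm - v[, 1],
             dl4_adj_mm = recording$dl4_mm - v[, 2])
}

#' Sensor features for the three movement directions
#'
#' The three scalar regressors of the estimator: the vertical-channel mean
#' `(dl1 + dl2)/2` for flexion-extension, the vertical difference
#' `dl1 - dl2` for side-bending, and the difference of the crosstalk-adjusted
#' oblique channels `dl3' - dl4'` for rotation.
#'
#' @inheritParams adjust_oblique
#' @return Data frame `time_s`, `f_fx_mm`, `f_sb_mm`, `f_rt_mm`.
#' @export
build_features <- function(recording, pairing = "ipsilateral") {
  adj <- adjust_oblique(recording, pairing)
  data.frame(time_s = recording$time_s,
             f_fx_mm = (recording$dl1_mm + recording$dl2_mm) / 2,
             f_sb_mm = recording$dl1_mm - recording$dl2_mm,
             f_rt_mm = adj$dl3_adj_mm - adj$dl4_adj_mm)
}

FEATURE_COLS <- c("f_fx_mm", "f_sb_mm", "f_rt_mm")

#' Calibrate the per-direction regression coefficients
#'
#' Fits one coefficient per movement direction by regressing the reference
#' angle on the matching sensor feature over a short window at the start of
#' the trial (default the first 10 s, half-open `[0, 10)`). The default fit
#' is through the origin - both series are displacement-zeroed at trial
#' start and the estimator has no intercept term; `include_intercept = TRUE`
#' switches to ordinary least squares.
#'
#' For an axis whose feature has no variation, calibration fails with a
#' named error unless the reference is also flat (an inactive axis), in
#' which case the coefficient is 0.
#'
#' @param features Feature data frame from [build_features()].
#' @param reference Reference `angle_series`, time-aligned with `features`.
#' @param fit_window_s Length-2 numeric: calibration window in seconds,
#'   half-open.
#' @param include_intercept Fit an intercept per axis.
#' @return A `calibration_model` with `alpha_deg_per_mm` (length-3 named),
#'   `intercept_deg`, `fit_window_s`, `include_intercept`.
#' @export
#' @examples
#' f <- data.frame(time_s = 0:2, f_fx_mm = 1:3, f_sb_mm = 1:3, f_rt_mm = 1:3)
#' ref <- data.frame(time_s = 0:2, fx_deg = c(2, 4, 6),
#'                   sb_deg = c(2, 4, 6), rt_deg = c(2, 4, 6))
#' calibrate(f, ref, fit_window_s = c(0, 3))$alpha_deg_per_mm
calibrate <- function(features, reference, fit_window_s = c(0, 10),
                      include_intercept = FALSE) {
  if (nrow(features) != nrow(reference) ||
      max(abs(features$time_s - reference$time_s)) > 1e-6) {
    lum_error("features and reference are not time-aligned",
              class = "lum_alignment_error")
  }
  if (fit_window_s[2] <= fit_window_s[1]) {
    lum_error("invalid calibration window", class = "lum_calibration_error")
  }
  idx <- which(features$time_s >= fit_window_s[1] - 1e-9 &
               features$time_s < fit_window_s[2] - 1e-9)
  if (length(idx) < 2) {
    lum_error("calibration window contains fewer than 2 samples",
              class = "lum_calibration_error")
  }
  alpha <- numeric(3)
  icpt <- numeric(3)
  for (k in 1:3) {
    f <- features[[FEATURE_COLS[k]]][idx]
    r <- reference[[AXES[k]]][idx]
    if (include_intercept) {
      if (stats::var(f) <= 1e-24) {
        if (sqrt(stats::var(r)) <= 1e-6) { alpha[k] <- 0; icpt[k] <- mean(r); next }
        lum_error(sprintf("no feature variation in calibration window (axis %s)",
                          AXES[k]), class = "lum_calibration_error")
      }
      fit <- stats::lm.fit(cbind(1, f), r)
      icpt[k] <- fit$coefficients[1]
      alpha[k] <- fit$coefficients[2]
    } else {
      ss <- sum(f^2)
      if (ss <= 1e-24) {
        if (sqrt(mean(r^2)) <= 1e-6) { alpha[k] <- 0; next }
        lum_error(sprintf("no feature variation in calibration window (axis %s)",
                          AXES[k]), class = "lum_calibration_error")
      }
      alpha[k] <- sum(f * r) / ss
    }
  }
  names(alpha) <- names(icpt) <- AXES
  structure(list(alpha_deg_per_mm = alpha,
                 intercept_deg = if (include_intercept) icpt else c(fx_deg = 0, sb_deg = 0, rt_deg = 0),
                 fit_window_s = fit_window_s,
                 include_intercept = include_intercept,
                 n_fit = length(idx)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Stretch-sensor calibration model\n")
  cat(sprintf("  window: [%g, %g) s  (%d samples)%s\n", x$fit_window_s[1],
              x$fit_window_s[2], x$n_fit,
              if (x$include_intercept) ", with intercept" else ""))
  cat(sprintf("  alpha1 (flexion-extension): %.4f deg/mm\n",
              x$alpha_deg_per_mm[["fx_deg"]]))
  cat(sprintf("  alpha2 (side-bending):      %.4f deg/mm\n",
              x$alpha_deg_per_mm[["sb_deg"]]))
  cat(sprintf("  alpha3 (rotation):          %.4f deg/mm\n",
              x$alpha_deg_per_mm[["rt_deg"]]))
  invisible(x)
}

#' Estimate lumbar angles from a sensor recording
#'
#' Applies the calibrated coefficients to the sensor features:
#' `fx = alpha1 * (dl1 + dl2)/2`, `sb = alpha2 * (dl1 - dl2)`,
#' `rt = alpha3 * (dl3' - dl4')` (plus intercepts when calibrated with one).
#'
#' @inheritParams adjust_oblique
#' @param model A `calibration_model` from [calibrate()].
#' @return An `angle_series` on the recording's time axis.
#' @export
estimate_angles <- function(recording, model, pairing = "ipsilateral") {
  if (!inherits(model, "calibration_model")) {
    lum_error("model must be a calibration_model", class = "lum_calibration_error")
  }
  ft <- build_features(recording, pairing)
  a <- model$alpha_deg_per_mm; b <- model$intercept_deg
  new_angle_series(ft$time_s,
                   a[["fx_deg"]] * ft$f_fx_mm + b[["fx_deg"]],
                   a[["sb_deg"]] * ft$f_sb_mm + b[["sb_deg"]],
                   a[["rt_deg"]] * ft$f_rt_mm + b[["rt_deg"]])
}

#' Run the full estimation pipeline on one trial
#'
#' End-to-end reproduction of the analysis chain: read (or accept) marker and
#' sensor data, align the streams, offset the sensor channels to trial start,
#' low-pass filter marker coordinates and sensor channels (zero-phase
#' Butterworth, default order 4 at 10 Hz), re-zero both streams at frame 0,
#' compute reference angles, calibrate on the first 10 s and estimate angles
#' over the whole trial.
#'
#' @param markers Marker data frame or path to a marker CSV/TRC file.
#' @param sensors Sensor data frame or path to a sensor CSV file.
#' @param cutoff_hz,filter_order Low-pass filter settings.
#' @param fit_window_s Calibration window, seconds (half-open).
#' @param pairing Oblique crosstalk pairing, see [adjust_oblique()].
#' @param include_intercept Calibrate with an intercept.
#' @param marker_filter `"angles"` (default) low-pass filters the reference
#'   angle series derived from the raw markers, keeping both streams under
#'   the identical linear operator (the premise of the linear calibration);
#'   `"coordinates"` filters the marker coordinates before the angle
#'   computation instead. The two differ by under 2e-4 degrees
#'   (edge-localized filter transients passed through the nonlinear angle
#'   computation).
#' @param verbose Log the fitted coefficients to stderr.
#' @return List of class `lumbar_pipeline_result`: `reference`, `estimated`
#'   (angle series), `calibration`, `features`, `fs_hz`.
#' @export
#' @examples
#' cfg <- sim_config(noise_sd_mm = 0, drift_mm_per_s = 0,
#'                   marker_noise_sd_mm = 0)
#' ang <- generate_angle_trajectory("FLEXION", cfg)
#' res <- run_pipeline(generate_markers(ang, cfg$skeleton),
#'                     forward_sensor_model(ang, cfg))
#' cor(res$reference$fx_deg, res$estimated$fx_deg)
run_pipeline <- function(markers, sensors, cutoff_hz = 10, filter_order = 4,
                         fit_window_s = c(0, 10), pairing = "ipsilateral",
                         include_intercept = FALSE,
                         marker_filter = c("angles", "coordinates"),
                         verbose = FALSE) {
  marker_filter <- match.arg(marker_filter)
  if (is.character(markers)) markers <- read_markers(markers)
  if (is.character(sensors)) sensors <- read_sensors(sensors)
  check_marker_frame(markers)
  check_sensor_recording(sensors)
  al <- align_streams(markers, sensors)
  markers <- al$markers; sensors <- al$sensors
  fs <- series_fs(sensors$time_s)
  if (max(sensors$time_s) + 1 / fs < fit_window_s[2]) {
    lum_error("trial shorter than the calibration window",
              class = "lum_calibration_error")
  }
  sensors <- filter_columns(sensors, SENSOR_COLS, fs, cutoff_hz, filter_order,
                            offset_before = TRUE, offset_after = TRUE)
  if (marker_filter == "coordinates") {
    marker_cols <- setdiff(names(markers), "time_s")
    markers <- filter_columns(markers, marker_cols, fs, cutoff_hz, filter_order)
    reference <- compute_reference_angles(markers, zero_first_frame = TRUE)
  } else {
    reference <- compute_reference_angles(markers, zero_first_frame = FALSE)
    reference <- filter_columns(reference, AXES, fs, cutoff_hz, filter_order,
                                offset_after = TRUE)
  }
  features <- build_features(sensors, pairing)
  model <- calibrate(features, reference, fit_window_s, include_intercept)
  estimated <- estimate_angles(sensors, model, pairing)
  if (verbose) {
    message(sprintf("calibration: alpha = (%.4f, %.4f, %.4f) deg/mm over [%g, %g) s",
                    model$alpha_deg_per_mm[1], model$alpha_deg_per_mm[2],
                    model$alpha_deg_per_mm[3],
                    fit_window_s[1], fit_window_s[2]))
  }
  structure(list(reference = reference, estimated = estimated,
                 calibration = model, features = features, fs_hz = fs),
            class = "lumbar_pipeline_result")
}
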