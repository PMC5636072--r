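# Agreement statistics: ROM, RMS error, Pearson correlation, error ratio and
# Bland-Altman limits of agreement.

check_angle_series <- function(x, what = "angle series") {
  missing <- setdiff(c("time_s", AXES), names(x))
  if (length(missing)) {
    lum_error(sprintf("%s missing columns: %s", what,
                      paste(missing, collapse = ", ")),
              class = "lum_schema_error", columns = missing)
  }
  invisible(x)
}

#' Range of motion per axis
#'
#' @param series An `angle_series` (or any data frame with `fx_deg`,
#'   `sb_deg`, `rt_deg`).
#' @return Named numeric vector of `max - min` per axis, degrees.
#' @export
#' @examples
#' rom(data.frame(time_s = 1:3, fx_deg = c(-5, 0, 10), sb_deg = 0, rt_deg = 0))
rom <- function(series) {
  check_angle_series(series)
  if (nrow(series) == 0) {
    lum_error("cannot compute ROM of an empty series",
              class = "lum_empty_series_error")
  }
  vapply(AXES, function(a) {
    v <- series[[a]]
    max(v) - min(v)
  }, numeric(1))
}

#' RMS error between actual and estimated angle series
#'
#' @param actual,estimated Angle series of equal length.
#' @return Named numeric vector of root-mean-square residuals per axis,
#'   degrees.
#' @export
rms_error <- function(actual, estimated) {
  check_angle_series(actual); check_angle_series(estimated)
  if (nrow(actual) != nrow(estimated)) {
    lum_error("actual and estimated series differ in length",
              class = "lum_alignment_error")
  }
  vapply(AXES, function(a) {
    sqrt(mean((estimated[[a]] - actual[[a]])^2))
  }, numeric(1))
}

#' Pearson correlation between actual and estimated angles
#'
#' Product-moment correlation per axis with a two-sided p-value from the
#' t-transform on `n - 2` degrees of freedom. Within-trial samples are
#' autocorrelated, so the p-value is anti-conservative; it is reported for
#' comparability, not inference.
#'
#' @param actual,estimated Angle series of equal length (>= 3 samples).
#' @return Data frame with `axis`, `r`, `p`.
#' @export
pearson <- function(actual, estimated) {
  check_angle_series(actual); check_angle_series(estimated)
  n <- nrow(actual)
  if (n != nrow(estimated)) {
    lum_error("actual and estimated series differ in length",
              class = "lum_alignment_error")
  }
  if (n < 3) {
    lum_error("need at least 3 samples for a correlation",
              class = "lum_schema_error")
  }
  res <- lapply(AXES, function(a) {
    pr <- pearson_xy(actual[[a]], estimated[[a]], a)
    data.frame(axis = a, r = pr[1], p = pr[2])
  })
  do.call(rbind, res)
}

pearson_xy <- function(x, y, axis = "") {
  # variance below 1e-16 (SD ~1e-8 deg) is numerical zero: no real motion
  if (stats::var(x) <= 1e-16 || stats::var(y) <= 1e-16) {
    lum_error(sprintf("zero variance on axis %s: correlation undefined", axis),
              class = "lum_zero_variance_error", axis = axis)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Error ratio of a trial
#'
#' RMS error as a percentage of the trial's range of motion. The study-level
#' aggregation applies it only to trials whose ROM exceeds two-thirds of the
#' subject's maximum ROM on that axis (large movements being the ones that
#' raise low-back-pain risk); see [build_report()].
#'
#' @param rms_deg RMS error, degrees.
#' @param rom_deg Range of motion, degrees.
#' @return `100 * rms / rom` (percent); `NA` with a warning when `rom` is 0.
#' @export
error_ratio <- function(rms_deg, rom_deg) {
  out <- ifelse(rom_deg > 0, 100 * rms_deg / rom_deg, NA_real_)
  if (anyNA(out)) warning("error ratio undefined for zero ROM")
  out
}

#' Bland-Altman agreement summary
#'
#' Differences `d = estimated - actual` of paired measurements; bias is
#' `mean(d)`, the limits of agreement are `bias +/- 1.96 * SD(d)` (sample SD,
#' n - 1 denominator), between which about 95% of differences are expected.
#'
#' @param estimated,actual Numeric vectors of paired measurements (>= 2
#'   pairs), e.g. per-trial ROM from the sensor and optical systems.
#' @return List of class `bland_altman`: `bias`, `sd`, `loa_low`, `loa_high`,
#'   `n_pairs`, `n_outside`, `points` (per-pair mean and difference) and
#'   `direction`.
#' @export
#' @examples
#' ba <- bland_altman(c(12, 9, 13), c(10, 10, 10))
#' ba$bias
bland_altman <- function(estimated, actual) {
  if (length(estimated) != length(actual)) {
    lum_error("paired measurements differ in length",
              class = "lum_alignment_error")
  }
  if (length(estimated) < 2) {
    lum_error("need at least 2 pairs for Bland-Altman analysis",
              class = "lum_schema_error")
  }
  d <- estimated - actual
  m <- (estimated + actual) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  structure(list(bias = bias, sd = s, loa_low = loa[1], loa_high = loa[2],
                 n_pairs = length(d),
                 n_outside = sum(d < loa[1] | d > loa[2]),
                 points = data.frame(mean = m, diff = d),
                 direction = "estimated - actual"),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.3f, SD %.3f, LoA [%.3f, %.3f], %d/%d outside\n",
              x$direction, x$bias, x$sd, x$loa_low, x$loa_high,
              x$n_outside, x$n_pairs))
  invisible(x)
}

#' Per-trial agreement statistics
#'
#' Computes ROM (actual and estimated), RMS error and Pearson r/p per axis
#' for one trial. Axes on which either series has zero variance get `NA`
#' correlations.
#'
#' @param reference,estimated Angle series of equal length.
#' @param subject,trial,condition Metadata carried into the result.
#' @return Data frame, one row per axis.
#' @export
evaluate_trial <- function(reference, estimated, subject = NA, trial = NA,
                           condition = NA) {
  rm_act <- rom(reference)
  rm_est <- rom(estimated)
  rms <- rms_error(reference, estimated)
  r <- p <- rep(NA_real_, 3)
  for (k in 1:3) {
    pr <- tryCatch(pearson_xy(reference[[AXES[k]]], estimated[[AXES[k]]],
                              AXES[k]),
                   lum_zero_variance_error = function(e) NULL)
    if (!is.null(pr)) { r[k] <- pr[[1]]; p[k] <- pr[[2]] }
  }
  data.frame(subject = subject, trial = trial, condition = condition,
             axis = AXES,
             rom_actual_deg = unname(rm_act), rom_est_deg = unname(rm_est),
             rms_error_deg = unname(rms), pearson_r = r, p_value = p,
             row.names = NULL)
}
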