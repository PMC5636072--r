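# Preprocessing: first-frame offset (angular/length displacement convention)
# and zero-phase low-pass Butterworth filtering.

#' Offset a series by its first sample
#'
#' Converts a raw channel into a displacement signal: `out[i] = x[i] - x[1]`,
#' so the first sample is exactly 0. Idempotent.
#'
#' @param x Numeric vector (non-empty).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' offset_first_frame(c(5, 6, 7))
offset_first_frame <- function(x) {
  if (length(x) == 0) {
    lum_error("cannot offset an empty series", class = "lum_empty_series_error")
  }
  x - x[1]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` low-pass Butterworth design (via
#' [signal::butter()]) forward and backward, giving zero phase lag and a
#' squared magnitude response. Edges are handled by odd-reflection padding of
#' length `3 * order` samples with step-steady-state initial conditions, so a
#' constant series is returned unchanged to machine precision.
#'
#' `order` is the order of the one-pass design; the effective attenuation of
#' the two passes is the square of its magnitude response.
#'
#' @param x Numeric vector.
#' @param fs_hz Sampling frequency, Hz.
#' @param cutoff_hz Cutoff frequency, Hz (must be below Nyquist).
#' @param order Filter order of the one-pass design.
#' @return Filtered vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 30, by = 0.01)
#' x <- sin(2 * pi * 0.125 * t)
#' y <- butterworth_lowpass(x, fs_hz = 100)
#' max(abs(y - x)) < 1e-3   # 0.125 Hz is deep in the passband
butterworth_lowpass <- function(x, fs_hz, cutoff_hz = 10, order = 4) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    lum_error("cutoff frequency must lie in (0, fs/2)",
              class = "lum_cutoff_error")
  }
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  b <- bf$b; a <- bf$a
  pad <- 3L * order
  nb <- length(b)
  n <- length(x)
  if (n < pad + nb + 1L) {
    lum_error(sprintf("series too short to filter (need >= %d samples, got %d)",
                      pad + nb + 1L, n), class = "lum_series_too_short_error")
  }
  one_pass <- function(x0) {
    # MA stage needs nb-1 samples of history: extend the left edge by
    # further odd reflection, then drop the warm-up outputs.
    ex <- 2 * x0[1] - x0[nb:2]
    v <- stats::filter(c(ex, x0), b, method = "convolution", sides = 1)
    v <- as.numeric(v)[nb:(length(x0) + nb - 1L)]
    # Recursive stage initialized at the DC steady state of the first padded
    # value (DC gain is 1), the step-response analogue of zi initialization.
    y <- stats::filter(v, -a[-1], method = "recursive",
                       init = rep(x0[1], length(a) - 1L))
    as.numeric(y)
  }
  xp <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  yf <- one_pass(xp)
  yb <- rev(one_pass(rev(yf)))
  yb[(pad + 1L):(pad + n)]
}

# Offset + filter every named column of a data frame (helper shared by the
# pipeline for marker coordinates and sensor channels).
filter_columns <- function(df, cols, fs_hz, cutoff_hz = 10, order = 4,
                           offset_before = FALSE, offset_after = FALSE) {
  for (cl in cols) {
    v <- df[[cl]]
    if (offset_before) v <- offset_first_frame(v)
    v <- butterworth_lowpass(v, fs_hz, cutoff_hz, order)
    if (offset_after) v <- offset_first_frame(v)
    df[[cl]] <- v
  }
  df
}

series_fs <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) == 0) {
    lum_error("time axis has fewer than 2 samples", class = "lum_schema_error")
  }
  if (max(dt) - min(dt) > tol || any(dt <= 0)) {
    lum_error("time axis is not uniformly sampled", class = "lum_schema_error")
  }
  1 / stats::median(dt)
}
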