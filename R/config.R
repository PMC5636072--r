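#' Default sensor gain matrix
#'
#' Linear sensitivity of the four stretch channels (rows: vertical right,
#' vertical left, oblique right, oblique left) to the three lumbar angles
#' (columns: flexion-extension, side-bending, rotation), in mm of length
#' displacement per degree.
#'
#' Structure encoded by the defaults:
#' * both vertical sensors load on flexion-extension with equal sign
#'   (0.9 mm/deg) and on side-bending with opposite signs (+/- 0.35 mm/deg);
#' * the vertical channels also carry an off-axis rotation crosstalk equal to
#'   `crosstalk_frac` of their flexion gain;
#' * each oblique channel carries its ipsilateral vertical channel's full
#'   loading (flexion, side-bending and the rotation crosstalk) plus its own
#'   rotation gain of +/- 0.5 mm/deg with opposite signs.
#'
#' Because the oblique rows equal the ipsilateral vertical rows plus a pure
#' rotation term, subtracting the vertical from the oblique channel cancels
#' the shared loading exactly - the premise of the crosstalk adjustment.
#' Magnitudes are chosen so protocol-scale angles stay within the 100%
#' dynamic range of a 70 mm sensor.
#'
#' @param vertical_fx_gain,vertical_sb_gain,oblique_rt_gain Gain magnitudes,
#'   mm/deg.
#' @param crosstalk_frac Fraction of the vertical flexion gain appearing as
#'   rotation crosstalk on the vertical channels.
#' @return 4 x 3 numeric matrix with dimnames.
#' @export
#' @examples
#' default_gain_matrix()
default_gain_matrix <- function(vertical_fx_gain = 0.9,
                                vertical_sb_gain = 0.35,
                                oblique_rt_gain = 0.5,
                                crosstalk_frac = 0.15) {
  v1 <- c(vertical_fx_gain,  vertical_sb_gain, crosstalk_frac * vertical_fx_gain)
  v2 <- c(vertical_fx_gain, -vertical_sb_gain, crosstalk_frac * vertical_fx_gain)
  g <- rbind(V1 = v1,
             V2 = v2,
             O3 = v1 + c(0, 0, oblique_rt_gain),
             O4 = v2 + c(0, 0, -oblique_rt_gain))
  colnames(g) <- AXES
  g
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study: trial timing, movement
#' amplitudes, the sensor gain matrix, noise and drift magnitudes, marker
#' noise, between-subject amplitude jitter, the RNG seed and the skeleton.
#'
#' Defaults reproduce the study conditions: 30 s trials sampled at 100 Hz,
#' movements at 0.125 Hz, per-condition amplitudes from
#' [default_amplitudes()], sensor noise SD 0.5 mm, marker noise SD 0.5 mm,
#' pre-strain drift -0.05 mm/s (slow shortening of the mounted sensors), and
#' lognormal between-subject amplitude jitter with sdlog 0.2.
#'
#' @param duration_s Trial duration, seconds.
#' @param fs_hz Sampling frequency, Hz.
#' @param movement_freq_hz Movement frequency, Hz (one cycle per 8 s).
#' @param amplitudes_deg 7 x 3 matrix of per-condition half-ROM amplitudes
#'   (degrees), rows named by condition id; default [default_amplitudes()].
#' @param gain_matrix_mm_per_deg 4 x 3 sensor gain matrix, mm/deg.
#' @param noise_sd_mm Additive Gaussian noise SD per sensor channel, mm.
#' @param drift_mm_per_s Linear pre-strain drift rate applied to every
#'   channel, mm/s (negative = shortening).
#' @param marker_noise_sd_mm Gaussian noise SD per marker coordinate, mm.
#' @param jitter_sdlog sdlog of the lognormal per-subject amplitude jitter
#'   (0 disables jitter).
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#' @param skeleton A [skeleton_template()].
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(noise_sd_mm = 0, drift_mm_per_s = 0)
#' cfg$fs_hz
sim_config <- function(duration_s = 30,
                       fs_hz = 100,
                       movement_freq_hz = 0.125,
                       amplitudes_deg = default_amplitudes(),
                       gain_matrix_mm_per_deg = default_gain_matrix(),
                       noise_sd_mm = 0.5,
                       drift_mm_per_s = -0.05,
                       marker_noise_sd_mm = 0.5,
                       jitter_sdlog = 0.2,
                       seed = 42L,
                       skeleton = skeleton_template()) {
  cfg <- list(duration_s = duration_s, fs_hz = fs_hz,
              movement_freq_hz = movement_freq_hz,
              amplitudes_deg = amplitudes_deg,
              gain_matrix_mm_per_deg = gain_matrix_mm_per_deg,
              noise_sd_mm = noise_sd_mm,
              drift_mm_per_s = drift_mm_per_s,
              marker_noise_sd_mm = marker_noise_sd_mm,
              jitter_sdlog = jitter_sdlog,
              seed = as.integer(seed),
              skeleton = skeleton)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg, filter_cutoff_hz = 10) {
  if (cfg$duration_s <= 0 || cfg$fs_hz <= 0 || cfg$movement_freq_hz <= 0) {
    lum_error("duration, sampling rate and movement frequency must be positive",
              class = "lum_config_error")
  }
  if (cfg$fs_hz <= 2 * filter_cutoff_hz) {
    lum_error("sampling rate must exceed twice the filter cutoff",
              class = "lum_config_error")
  }
  a <- cfg$amplitudes_deg
  if (!is.matrix(a) || ncol(a) != 3 ||
      !all(CONDITION_IDS %in% rownames(a))) {
    lum_error("amplitudes_deg must be a matrix with one named row per condition",
              class = "lum_config_error")
  }
  if (any(a < 0) || !all(is.finite(a))) {
    lum_error("amplitudes must be finite and non-negative",
              class = "lum_config_error")
  }
  check_gain_matrix(cfg$gain_matrix_mm_per_deg)
  if (cfg$noise_sd_mm < 0 || cfg$marker_noise_sd_mm < 0 || cfg$jitter_sdlog < 0) {
    lum_error("noise SDs and jitter sdlog must be non-negative",
              class = "lum_config_error")
  }
  validate_skeleton(cfg$skeleton)
  invisible(cfg)
}

check_gain_matrix <- function(g) {
  if (!is.matrix(g) || !all(dim(g) == c(4, 3)) || !all(is.finite(g))) {
    lum_error("gain matrix must be a finite 4 x 3 matrix (channels x axes)",
              class = "lum_gain_error")
  }
  invisible(g)
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [sim_config()] field-for-field; absent fields keep their
#' defaults. `amplitudes_deg` may be a mapping from condition id to a 3-vector
#' and `gain_matrix_mm_per_deg` a list of 4 rows.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    lum_error(sprintf("config file not found: %s", path),
              class = "lum_io_error")
  }
  y <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("duration_s", "fs_hz", "movement_freq_hz", "noise_sd_mm",
               "drift_mm_per_s", "marker_noise_sd_mm", "jitter_sdlog", "seed")
  for (s in scalars) if (!is.null(y[[s]])) args[[s]] <- y[[s]]
  if (!is.null(y$amplitudes_deg)) {
    a <- default_amplitudes()
    for (id in names(y$amplitudes_deg)) {
      a[match_condition(id), ] <- as.numeric(y$amplitudes_deg[[id]])
    }
    args$amplitudes_deg <- a
  }
  if (!is.null(y$gain_matrix_mm_per_deg)) {
    g <- do.call(rbind, lapply(y$gain_matrix_mm_per_deg, as.numeric))
    rownames(g) <- c("V1", "V2", "O3", "O4")[seq_len(nrow(g))]
    colnames(g) <- AXES[seq_len(ncol(g))]
    args$gain_matrix_mm_per_deg <- g
  }
  do.call(sim_config, args)
}
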