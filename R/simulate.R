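# Synthetic study generator: sinusoidal lumbar-angle trajectories, the
# marker forward model (rigid trunk rotation about the lumbar joint center)
# and the linear sensor forward model with crosstalk, drift and noise.

new_angle_series <- function(time_s, fx_deg, sb_deg, rt_deg) {
  structure(data.frame(time_s = time_s, fx_deg = fx_deg,
                       sb_deg = sb_deg, rt_deg = rt_deg),
            class = c("angle_series", "data.frame"))
}

time_axis <- function(config) {
  n <- round(config$duration_s * config$fs_hz)
  (seq_len(n) - 1) / config$fs_hz
}

#' Generate a lumbar-angle trajectory for one movement condition
#'
#' Each active axis follows `A * sin(2*pi*f*t + phi)` with the condition's
#' half-ROM amplitude A; inactive axes are identically zero. The
#' circumduction condition drives flexion and side-bending 90 degrees out of
#' phase, tracing a circle in the FX-SB plane.
#'
#' @param condition Condition id, one of `movement_conditions()$id`.
#' @param config A [sim_config()].
#' @param amplitudes_deg Optional length-3 override of the condition's
#'   amplitudes (degrees), in axis order fx, sb, rt.
#' @return An `angle_series` data frame: `time_s`, `fx_deg`, `sb_deg`,
#'   `rt_deg`.
#' @export
#' @examples
#' ang <- generate_angle_trajectory("FLEXION", sim_config())
#' max(ang$fx_deg) - min(ang$fx_deg)  # peak-to-peak ROM = 33.82 deg
generate_angle_trajectory <- function(condition, config = sim_config(),
                                      amplitudes_deg = NULL) {
  condition <- match_condition(condition)
  validate_sim_config(config)
  amps <- if (is.null(amplitudes_deg)) {
    config$amplitudes_deg[condition, ]
  } else {
    stopifnot(length(amplitudes_deg) == 3)
    as.numeric(amplitudes_deg)
  }
  phases <- condition_phases()[condition, ]
  t <- time_axis(config)
  w <- 2 * pi * config$movement_freq_hz
  th <- vapply(1:3, function(k) {
    amps[[k]] * sin(w * t + phases[[k]] * pi / 180)
  }, numeric(length(t)))
  new_angle_series(t, th[, 1], th[, 2], th[, 3])
}

rot_x <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Forward marker model: rigid trunk rotation about the lumbar joint
#'
#' Pelvis markers stay at their template positions; trunk markers are rotated
#' about the lumbar joint center by `R(t) = Rx(fx) %*% Ry(sb) %*% Rz(rt)`.
#' Optional i.i.d. Gaussian noise is added to every coordinate.
#'
#' @param angles An `angle_series`.
#' @param skeleton A [skeleton_template()].
#' @param marker_noise_sd_mm Noise SD per coordinate, mm.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Marker trajectories: data frame `time_s` plus `<MARKER>_x/_y/_z`
#'   columns in mm.
#' @export
generate_markers <- function(angles, skeleton = skeleton_template(),
                             marker_noise_sd_mm = 0, seed = NULL) {
  lum_stopifnot_finite(angles[AXES], "angle series")
  validate_skeleton(skeleton)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(angles)
  fx <- angles$fx_deg * pi / 180
  sb <- angles$sb_deg * pi / 180
  rt <- angles$rt_deg * pi / 180
  # Row-expanded R(t) = Rx(fx) Ry(sb) Rz(rt), vectorized over frames.
  cf <- cos(fx); sf <- sin(fx); cb <- cos(sb); sbn <- sin(sb)
  cg <- cos(rt); sg <- sin(rt)
  r11 <- cb * cg;                 r12 <- -cb * sg;                r13 <- sbn
  r21 <- cf * sg + sf * sbn * cg; r22 <- cf * cg - sf * sbn * sg; r23 <- -sf * cb
  r31 <- sf * sg - cf * sbn * cg; r32 <- sf * cg + cf * sbn * sg; r33 <- cf * cb

  out <- data.frame(time_s = angles$time_s)
  jc <- skeleton$joint_center
  for (m in MARKER_NAMES) {
    p0 <- skeleton$landmarks[m, ]
    if (m %in% skeleton$trunk_markers) {
      v <- p0 - jc
      px <- jc[1] + r11 * v[1] + r12 * v[2] + r13 * v[3]
      py <- jc[2] + r21 * v[1] + r22 * v[2] + r23 * v[3]
      pz <- jc[3] + r31 * v[1] + r32 * v[2] + r33 * v[3]
    } else {
      px <- rep(p0[1], n); py <- rep(p0[2], n); pz <- rep(p0[3], n)
    }
    if (marker_noise_sd_mm > 0) {
      px <- px + stats::rnorm(n, 0, marker_noise_sd_mm)
      py <- py + stats::rnorm(n, 0, marker_noise_sd_mm)
      pz <- pz + stats::rnorm(n, 0, marker_noise_sd_mm)
    }
    out[[paste0(m, "_x")]] <- px
    out[[paste0(m, "_y")]] <- py
    out[[paste0(m, "_z")]] <- pz
  }
  out
}

#' Forward sensor model: linear gain map plus drift and noise
#'
#' Channel displacements are `dl(t) = G %*% theta(t) + drift * t + eps(t)`
#' with `eps ~ N(0, noise_sd^2)` i.i.d. per channel and sample. With the
#' default gain matrix the oblique channels inherit their ipsilateral
#' vertical channel's loading, so the crosstalk adjustment of the estimator
#' cancels it exactly.
#'
#' @param angles An `angle_series`.
#' @param config A [sim_config()]; uses its gain matrix, noise SD and drift.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Sensor recording: data frame `time_s`, `dl1_mm` ... `dl4_mm` (mm).
#' @export
#' @examples
#' cfg <- sim_config(noise_sd_mm = 0, drift_mm_per_s = 0)
#' rec <- forward_sensor_model(generate_angle_trajectory("FLEXION", cfg), cfg)
forward_sensor_model <- function(angles, config = sim_config(), seed = NULL) {
  g <- check_gain_matrix(config$gain_matrix_mm_per_deg)
  lum_stopifnot_finite(angles[AXES], "angle series")
  if (!is.null(seed)) set.seed(as.integer(seed))
  th <- as.matrix(angles[AXES])
  dl <- th %*% t(g)
  n <- nrow(dl)
  drift <- config$drift_mm_per_s * angles$time_s
  out <- data.frame(time_s = angles$time_s)
  for (k in 1:4) {
    ch <- dl[, k] + drift
    if (config$noise_sd_mm > 0) {
      ch <- ch + stats::rnorm(n, 0, config$noise_sd_mm)
    }
    out[[paste0("dl", k, "_mm")]] <- ch
  }
  out
}

#' Capacitance model of the sheet sensor
#'
#' The sensor is a parallel-plate capacitor over an incompressible elastomer:
#' capacitance is proportional to the square of the sensing area, and at
#' constant width the area is proportional to length, so `C = c0 * (l/l0)^2`.
#' `capacitance_to_length()` inverts the map.
#'
#' @param length_mm Sensor length, mm (> 0).
#' @param initial_length_mm Mounted length l0, mm.
#' @param c0_pF Capacitance at the mounted length, pF.
#' @return Capacitance in pF, or length in mm for the inverse.
#' @export
#' @examples
#' length_to_capacitance(105, 70, 100)  # (1.5)^2 * 100 = 225 pF
length_to_capacitance <- function(length_mm, initial_length_mm = 70,
                                  c0_pF = 100) {
  if (any(length_mm <= 0) || initial_length_mm <= 0 || c0_pF <= 0) {
    lum_error("lengths and base capacitance must be positive",
              class = "lum_capacitance_error")
  }
  c0_pF * (length_mm / initial_length_mm)^2
}

#' @rdname length_to_capacitance
#' @param capacitance_pF Capacitance, pF (> 0 for inversion).
#' @export
capacitance_to_length <- function(capacitance_pF, initial_length_mm = 70,
                                  c0_pF = 100) {
  if (any(capacitance_pF <= 0) || initial_length_mm <= 0 || c0_pF <= 0) {
    lum_error("capacitance must be positive to invert the area model",
              class = "lum_capacitance_error")
  }
  initial_length_mm * sqrt(capacitance_pF / c0_pF)
}

#' Simulate a full study
#'
#' Generates `n_subjects` x 7 trials (one per movement condition). Each
#' subject's active-axis amplitudes are jittered by a lognormal factor
#' (`exp(rnorm(0, jitter_sdlog))`) around the condition defaults to emulate
#' between-subject ROM spread; all randomness derives from `config$seed`, so
#' identical configs give bit-identical studies.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of simulated subjects (>= 1).
#' @return List of trials; each has `subject`, `trial`, `condition`,
#'   `amplitudes_deg`, `truth` (angle series), `markers`, `sensors`.
#' @export
#' @examples
#' trials <- simulate_study(sim_config(), n_subjects = 1)
#' length(trials)
simulate_study <- function(config = sim_config(), n_subjects = 6) {
  validate_sim_config(config)
  if (n_subjects < 1) {
    lum_error("n_subjects must be >= 1", class = "lum_config_error")
  }
  set.seed(config$seed)
  conds <- CONDITION_IDS
  # Draw jitter and per-trial noise seeds up-front from the master stream.
  jitter <- array(1, dim = c(n_subjects, length(conds), 3))
  if (config$jitter_sdlog > 0) {
    jitter <- array(exp(stats::rnorm(length(jitter), 0, config$jitter_sdlog)),
                    dim = dim(jitter))
  }
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_subjects * length(conds) * 2),
                        ncol = 2)
  out <- vector("list", n_subjects * length(conds))
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (ci in seq_along(conds)) {
      i <- i + 1L
      base <- config$amplitudes_deg[conds[ci], ]
      amps <- as.numeric(base) * jitter[s, ci, ]
      angles <- generate_angle_trajectory(conds[ci], config,
                                          amplitudes_deg = amps)
      markers <- generate_markers(angles, config$skeleton,
                                  config$marker_noise_sd_mm,
                                  seed = trial_seeds[i, 1])
      sensors <- forward_sensor_model(angles, config,
                                      seed = trial_seeds[i, 2])
      out[[i]] <- list(subject = s, trial = ci, condition = conds[ci],
                       amplitudes_deg = amps, truth = angles,
                       markers = markers, sensors = sensors)
    }
  }
  out
}
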