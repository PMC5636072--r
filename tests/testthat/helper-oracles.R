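# Independent oracles and shared fixtures for the test suite.

# Rotation matrices built directly from their textbook definitions; these are
# deliberately separate from the package internals so compose-then-decompose
# checks have an independent reference.
oracle_rx <- function(deg) {
  a <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
}
oracle_ry <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
}
oracle_rz <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}
oracle_cardan_compose <- function(fx, sb, rt) {
  oracle_rx(fx) %*% oracle_ry(sb) %*% oracle_rz(rt)
}

# Apply a rigid rotation (about an optional pivot) to every marker of a
# trajectory data frame.
rotate_markers <- function(markers, r0, pivot = c(0, 0, 0),
                           which = lumbarstretch::MARKER_NAMES) {
  for (m in which) {
    p <- cbind(markers[[paste0(m, "_x")]], markers[[paste0(m, "_y")]],
               markers[[paste0(m, "_z")]])
    p <- sweep(sweep(p, 2, pivot) %*% t(r0), 2, pivot, `+`)
    markers[[paste0(m, "_x")]] <- p[, 1]
    markers[[paste0(m, "_y")]] <- p[, 2]
    markers[[paste0(m, "_z")]] <- p[, 3]
  }
  markers
}

# Noise-free study configuration (the linear-model limit).
quiet_config <- function(...) {
  args <- list(noise_sd_mm = 0, drift_mm_per_s = 0, marker_noise_sd_mm = 0,
               jitter_sdlog = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Single-frame angle series helper.
one_frame_angles <- function(fx = 0, sb = 0, rt = 0) {
  data.frame(time_s = 0, fx_deg = fx, sb_deg = sb, rt_deg = rt)
}
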