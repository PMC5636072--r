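# Synthetic study generator: angle trajectories, marker and sensor forward
# models, capacitance map, study assembly.

test_that("uniaxial trajectories are sinusoids with the configured ROM", {
  cfg <- quiet_config()
  ang <- generate_angle_trajectory("FLEXION", cfg)
  expect_equal(nrow(ang), 3000)
  expect_equal(max(ang$fx_deg) - min(ang$fx_deg), 33.82, tolerance = 1e-9)
  expect_true(all(ang$sb_deg == 0) && all(ang$rt_deg == 0))
  expect_equal(ang$fx_deg[1], 0)
  # ROM = 2A for a few amplitudes on another axis
  for (a in c(1, 5.61, 20)) {
    tr <- generate_angle_trajectory("ROTATION", cfg,
                                    amplitudes_deg = c(0, 0, a))
    expect_equal(max(tr$rt_deg) - min(tr$rt_deg), 2 * a, tolerance = 1e-9)
  }
})

test_that("zero amplitudes give an all-zero series of the full length", {
  ang <- generate_angle_trajectory("SIDE_BENDING", quiet_config(),
                                   amplitudes_deg = c(0, 0, 0))
  expect_equal(nrow(ang), 3000)
  expect_true(all(as.matrix(ang[c("fx_deg", "sb_deg", "rt_deg")]) == 0))
})

test_that("circumduction traces a circle in the FX-SB plane", {
  ang <- generate_angle_trajectory("CRANIAL_CAUDAL_CIRCUMDUCTION",
                                   quiet_config(),
                                   amplitudes_deg = c(10, 10, 0))
  radius2 <- ang$fx_deg^2 / 100 + ang$sb_deg^2 / 100
  expect_lt(max(radius2) - min(radius2), 1e-9)
})

test_that("unknown movement conditions are rejected", {
  expect_error(generate_angle_trajectory("TWIST", quiet_config()),
               class = "lum_condition_error")
})

test_that("marker forward model is the rigid rotation it claims", {
  sk <- skeleton_template()
  # identity rotation: all markers constant at template positions
  ang0 <- generate_angle_trajectory("FLEXION", quiet_config(),
                                    amplitudes_deg = c(0, 0, 0))
  mk <- generate_markers(ang0, sk, marker_noise_sd_mm = 0)
  for (m in MARKER_NAMES) {
    expect_equal(unique(mk[[paste0(m, "_x")]]), sk$landmarks[m, "x"],
                 ignore_attr = TRUE)
    expect_equal(unique(mk[[paste0(m, "_z")]]), sk$landmarks[m, "z"],
                 ignore_attr = TRUE)
  }
  # single frame at 10 deg flexion: C7 equals the oracle rotation result
  mk1 <- generate_markers(one_frame_angles(fx = 10), sk)
  expected <- as.numeric(oracle_rx(10) %*% (sk$landmarks["C7", ] -
                                              sk$joint_center) +
                           sk$joint_center)
  got <- c(mk1$C7_x, mk1$C7_y, mk1$C7_z)
  expect_equal(got, expected, tolerance = 1e-12)
  # pelvis markers never move
  mk2 <- generate_markers(one_frame_angles(fx = 25, sb = -10, rt = 15), sk)
  expect_equal(c(mk2$ASIS_R_x, mk2$ASIS_R_y, mk2$ASIS_R_z),
               as.numeric(sk$landmarks["ASIS_R", ]))
})

test_that("trunk marker distances are preserved under rotation", {
  sk <- skeleton_template()
  ang <- generate_angle_trajectory("ROTATION", quiet_config(),
                                   amplitudes_deg = c(0, 0, 20))
  mk <- generate_markers(ang, sk, marker_noise_sd_mm = 0)
  d0 <- sqrt(sum((sk$landmarks["ACR_R", ] - sk$landmarks["ACR_L", ])^2))
  d <- sqrt((mk$ACR_R_x - mk$ACR_L_x)^2 + (mk$ACR_R_y - mk$ACR_L_y)^2 +
              (mk$ACR_R_z - mk$ACR_L_z)^2)
  expect_lt(max(abs(d - d0)), 1e-9)
  # all pairwise trunk distances, spot-checked over time
  pairs <- utils::combn(sk$trunk_markers, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d0 <- sqrt(sum((sk$landmarks[a, ] - sk$landmarks[b, ])^2))
    d <- sqrt((mk[[paste0(a, "_x")]] - mk[[paste0(b, "_x")]])^2 +
                (mk[[paste0(a, "_y")]] - mk[[paste0(b, "_y")]])^2 +
                (mk[[paste0(a, "_z")]] - mk[[paste0(b, "_z")]])^2)
    expect_lt(max(abs(d - d0)), 1e-9)
  }
})

test_that("sensor forward model is the stated linear map", {
  cfg <- quiet_config()
  # constant 10 deg flexion, vertical FX gain 0.9 -> both verticals read 9 mm
  ang <- data.frame(time_s = (0:9) / 100, fx_deg = 10, sb_deg = 0, rt_deg = 0)
  rec <- forward_sensor_model(ang, cfg)
  expect_equal(rec$dl1_mm, rep(9, 10), tolerance = 1e-12)
  expect_equal(rec$dl2_mm, rep(9, 10), tolerance = 1e-12)
  # pure drift: every channel reads -3 mm at t = 30 s
  cfgd <- quiet_config(drift_mm_per_s = -0.1)
  ang0 <- generate_angle_trajectory("FLEXION", cfgd,
                                    amplitudes_deg = c(0, 0, 0))
  ang0 <- rbind(ang0, data.frame(time_s = 30, fx_deg = 0, sb_deg = 0,
                                 rt_deg = 0))
  recd <- forward_sensor_model(ang0, cfgd)
  last <- nrow(recd)
  for (ch in c("dl1_mm", "dl2_mm", "dl3_mm", "dl4_mm")) {
    expect_equal(recd[[ch]][last], -3, tolerance = 1e-12)
  }
  # crosstalk construction: oblique minus ipsilateral vertical vanishes on a
  # flexion-only input
  angf <- generate_angle_trajectory("FLEXION", cfg)
  recf <- forward_sensor_model(angf, cfg)
  expect_lt(max(abs(recf$dl3_mm - recf$dl1_mm)), 1e-12)
  expect_lt(max(abs(recf$dl4_mm - recf$dl2_mm)), 1e-12)
})

test_that("noise- and drift-free sensor outputs are linear in the angles", {
  cfg <- quiet_config()
  a1 <- generate_angle_trajectory("FLEXION", cfg)
  a2 <- generate_angle_trajectory("ROTATION", cfg)
  sum_ang <- a1
  for (ax in c("fx_deg", "sb_deg", "rt_deg")) {
    sum_ang[[ax]] <- 2 * a1[[ax] ] + 3 * a2[[ax]]
  }
  r1 <- forward_sensor_model(a1, cfg)
  r2 <- forward_sensor_model(a2, cfg)
  rs <- forward_sensor_model(sum_ang, cfg)
  for (ch in c("dl1_mm", "dl2_mm", "dl3_mm", "dl4_mm")) {
    expect_equal(rs[[ch]], 2 * r1[[ch]] + 3 * r2[[ch]], tolerance = 1e-12)
  }
})

test_that("a wrongly shaped gain matrix is rejected", {
  cfg <- quiet_config()
  cfg$gain_matrix_mm_per_deg <- matrix(1, 3, 3)
  ang <- generate_angle_trajectory("FLEXION", quiet_config())
  expect_error(forward_sensor_model(ang, cfg), class = "lum_gain_error")
})

test_that("capacitance follows the squared-length model and inverts", {
  expect_equal(length_to_capacitance(70, 70, 100), 100)
  expect_equal(length_to_capacitance(105, 70, 100), 225)
  set.seed(7)
  x <- runif(100, 0.5 * 70, 2 * 70)
  back <- capacitance_to_length(length_to_capacitance(x))
  expect_equal(back, x, tolerance = 1e-12)
  expect_error(capacitance_to_length(-5), class = "lum_capacitance_error")
})

test_that("simulate_study assembles the protocol deterministically", {
  cfg <- sim_config(seed = 11)
  trials <- simulate_study(cfg, n_subjects = 6)
  expect_length(trials, 42)
  expect_true(all(vapply(trials, function(t) nrow(t$truth), 0L) == 3000))
  expect_equal(vapply(trials[1:7], `[[`, "", "condition"),
               movement_conditions()$id)
  trials2 <- simulate_study(cfg, n_subjects = 6)
  expect_identical(trials, trials2)
  # without jitter and noise, trial 1 true flexion ROM is exactly 33.82 deg
  q <- simulate_study(quiet_config(seed = 3), n_subjects = 1)
  expect_equal(max(q[[1]]$truth$fx_deg) - min(q[[1]]$truth$fx_deg), 33.82,
               tolerance = 1e-9)
})
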