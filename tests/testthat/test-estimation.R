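# The estimator: crosstalk adjustment, features, calibration, angle
# reconstruction and the end-to-end pipeline.

make_rec <- function(dl1, dl2, dl3, dl4) {
  n <- length(dl1)
  data.frame(time_s = (seq_len(n) - 1) / 100, dl1_mm = dl1, dl2_mm = dl2,
             dl3_mm = dl3, dl4_mm = dl4)
}

test_that("oblique adjustment subtracts the paired vertical channel", {
  rec <- make_rec(c(0.5, 0.5), c(1, 1), c(1, 2), c(3, 4))
  adj <- adjust_oblique(rec)
  expect_equal(adj$dl3_adj_mm, c(0.5, 1.5))
  expect_equal(adj$dl4_adj_mm, c(2, 3))
  # identical channels cancel exactly
  rec2 <- make_rec(c(1, 2, 3), c(4, 5, 6), c(1, 2, 3), c(4, 5, 6))
  adj2 <- adjust_oblique(rec2)
  expect_true(all(adj2$dl3_adj_mm == 0) && all(adj2$dl4_adj_mm == 0))
  # contralateral pairing swaps the verticals
  adjc <- adjust_oblique(rec, pairing = "contralateral")
  expect_equal(adjc$dl3_adj_mm, c(0, 1))
  # simulated flexion trial: crosstalk construction cancels completely
  cfg <- quiet_config()
  recf <- forward_sensor_model(generate_angle_trajectory("FLEXION", cfg), cfg)
  adjf <- adjust_oblique(recf)
  expect_lt(max(abs(adjf$dl3_adj_mm)), 1e-12)
  expect_lt(max(abs(adjf$dl4_adj_mm)), 1e-12)
})

test_that("features are the stated channel combinations", {
  rec <- make_rec(2, 4, 1, 1)
  ft <- build_features(rec)
  expect_equal(ft$f_fx_mm, 3)
  expect_equal(ft$f_sb_mm, -2)
  # symmetric flexion leaves no side-bending feature
  recs <- make_rec(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0), c(0, 0, 0))
  expect_true(all(build_features(recs)$f_sb_mm == 0))
  # rotation trial: flexion/side-bending features stay within the crosstalk
  # fraction of a flexion trial's, rotation feature tracks the truth
  cfg <- quiet_config()
  ang_rt <- generate_angle_trajectory("ROTATION", cfg)
  ft_rt <- build_features(forward_sensor_model(ang_rt, cfg))
  ang_fx <- generate_angle_trajectory("FLEXION", cfg)
  ft_fx <- build_features(forward_sensor_model(ang_fx, cfg))
  expect_lt(max(abs(ft_rt$f_fx_mm)), 0.15 * max(abs(ft_fx$f_fx_mm)))
  expect_lt(max(abs(ft_rt$f_sb_mm)), 1e-12)
  expect_gt(stats::cor(ft_rt$f_rt_mm, ang_rt$rt_deg), 0.999999)
})

test_that("calibration recovers slopes through the origin", {
  f <- data.frame(time_s = 0:2, f_fx_mm = c(1, 2, 3), f_sb_mm = c(1, 2, 3),
                  f_rt_mm = c(1, 2, 3))
  ref <- data.frame(time_s = 0:2, fx_deg = c(2, 4, 6), sb_deg = c(2, 4, 6),
                    rt_deg = c(2, 4, 6))
  m <- calibrate(f, ref, fit_window_s = c(0, 3))
  expect_equal(unname(m$alpha_deg_per_mm), rep(2, 3))
  # all-zero reference gives zero coefficients
  ref0 <- ref
  ref0[c("fx_deg", "sb_deg", "rt_deg")] <- 0
  expect_equal(unname(calibrate(f, ref0,
                                fit_window_s = c(0, 3))$alpha_deg_per_mm),
               rep(0, 3))
  # flat features against a moving reference cannot be calibrated
  fflat <- f
  fflat[c("f_fx_mm", "f_sb_mm", "f_rt_mm")] <- 0
  expect_error(calibrate(fflat, ref, fit_window_s = c(0, 3)),
               class = "lum_calibration_error")
})

test_that("calibration inverts the known simulator gain", {
  cfg <- quiet_config()
  ang <- generate_angle_trajectory("FLEXION", cfg)
  rec <- forward_sensor_model(ang, cfg)
  ft <- build_features(rec)
  m <- calibrate(ft, ang, fit_window_s = c(0, 10))
  expect_equal(m$alpha_deg_per_mm[["fx_deg"]], 1 / 0.9, tolerance = 1e-6)
})

test_that("intercept calibration reproduces ordinary least squares", {
  set.seed(31)
  f <- data.frame(time_s = (0:99) / 100, f_fx_mm = rnorm(100),
                  f_sb_mm = rnorm(100), f_rt_mm = rnorm(100))
  ref <- data.frame(time_s = f$time_s,
                    fx_deg = 1.5 * f$f_fx_mm + 2 + rnorm(100, 0, 0.1),
                    sb_deg = -0.7 * f$f_sb_mm - 1 + rnorm(100, 0, 0.1),
                    rt_deg = 0.3 * f$f_rt_mm + rnorm(100, 0, 0.1))
  m <- calibrate(f, ref, fit_window_s = c(0, 1), include_intercept = TRUE)
  ls <- stats::lm(ref$fx_deg ~ f$f_fx_mm)
  expect_equal(m$alpha_deg_per_mm[["fx_deg"]],
               unname(stats::coef(ls)[2]), tolerance = 1e-9)
  expect_equal(m$intercept_deg[["fx_deg"]], unname(stats::coef(ls)[1]),
               tolerance = 1e-9)
})

test_that("estimate_angles applies the calibrated linear map", {
  rec0 <- make_rec(rep(0, 5), rep(0, 5), rep(0, 5), rep(0, 5))
  m <- structure(list(alpha_deg_per_mm = c(fx_deg = 1.111, sb_deg = 2,
                                           rt_deg = 3),
                      intercept_deg = c(fx_deg = 0, sb_deg = 0, rt_deg = 0),
                      fit_window_s = c(0, 10), include_intercept = FALSE,
                      n_fit = 5),
                 class = "calibration_model")
  est0 <- estimate_angles(rec0, m)
  expect_true(all(as.matrix(est0[c("fx_deg", "sb_deg", "rt_deg")]) == 0))
  rec <- make_rec(9, 9, 9, 9)   # f_fx = 9, f_sb = 0, f_rt = 0
  est <- estimate_angles(rec, m)
  expect_equal(est$fx_deg, 1.111 * 9)
})

test_that("estimates are equivariant to a common channel rescaling", {
  cfg <- quiet_config()
  ang <- generate_angle_trajectory("SIDEBENDING_FLEXION", cfg)
  rec <- forward_sensor_model(ang, cfg)
  ft <- build_features(rec)
  m <- calibrate(ft, ang, fit_window_s = c(0, 10))
  rec2 <- rec
  for (ch in c("dl1_mm", "dl2_mm", "dl3_mm", "dl4_mm")) {
    rec2[[ch]] <- 4 * rec2[[ch]]
  }
  ft2 <- build_features(rec2)
  m2 <- calibrate(ft2, ang, fit_window_s = c(0, 10))
  expect_equal(unname(m2$alpha_deg_per_mm[c(1, 2)]),
               unname(m$alpha_deg_per_mm[c(1, 2)]) / 4, tolerance = 1e-9)
  est <- estimate_angles(rec, m)
  est2 <- estimate_angles(rec2, m2)
  expect_equal(est2$fx_deg, est$fx_deg, tolerance = 1e-9)
  expect_equal(est2$sb_deg, est$sb_deg, tolerance = 1e-9)
})

test_that("side-bending estimate ignores common-mode vertical signal", {
  cfg <- quiet_config()
  ang <- generate_angle_trajectory("SIDE_BENDING", cfg)
  rec <- forward_sensor_model(ang, cfg)
  rec2 <- rec
  common <- 3 * sin(2 * pi * 0.5 * rec$time_s)
  rec2$dl1_mm <- rec2$dl1_mm + common
  rec2$dl2_mm <- rec2$dl2_mm + common
  expect_equal(build_features(rec2)$f_sb_mm, build_features(rec)$f_sb_mm,
               tolerance = 1e-12)
})

test_that("the noiseless pipeline recovers the true angles exactly", {
  cfg <- quiet_config()
  trial <- simulate_study(cfg, n_subjects = 1)[[6]]  # side-bending + flexion
  res <- run_pipeline(trial$markers, trial$sensors)
  rms <- rms_error(res$reference, res$estimated)
  expect_lt(max(rms), 1e-6)
  expect_gt(stats::cor(res$reference$fx_deg, res$estimated$fx_deg),
            0.9999999)
  expect_gt(stats::cor(res$reference$sb_deg, res$estimated$sb_deg),
            0.9999999)
})

test_that("trials shorter than the calibration window are rejected", {
  cfg <- quiet_config(duration_s = 5)
  ang <- generate_angle_trajectory("FLEXION", cfg)
  mk <- generate_markers(ang, cfg$skeleton)
  rec <- forward_sensor_model(ang, cfg)
  expect_error(run_pipeline(mk, rec), class = "lum_calibration_error")
})

test_that("the default noisy pipeline runs clean and reports finite errors", {
  cfg <- sim_config(seed = 8)
  trial <- simulate_study(cfg, n_subjects = 1)[[1]]
  res <- run_pipeline(trial$markers, trial$sensors)
  rms <- rms_error(res$reference, res$estimated)
  expect_true(all(is.finite(rms)) && all(rms > 0))
})
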