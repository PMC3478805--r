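test_that("noiseless trajectory reaches exactly the drawn drop depth", {
  p <- gait_profile(n_steps = 1, nd_mean_mm = 5, nd_sd_mm = 0,
                    noise_nh_mm = 0, noise_cap_pf = 0, seed = 1)
  traj <- simulate_nh_trajectory(p, 200)
  # the continuous template attains the depth exactly at the truth time
  expect_equal(traj$nh_fun(traj$truth$t_nhl_s), p$nh_baseline_mm - 5.0)
  expect_equal(traj$truth$nd_true_mm, 5.0)
  # the sampled series comes within half-sample curvature of it
  expect_equal(min(traj$nh_mm), p$nh_baseline_mm - 5.0, tolerance = 1e-3)

  p0 <- gait_profile(n_steps = 3, nd_mean_mm = 0, nd_sd_mm = 0,
                     noise_nh_mm = 0, noise_cap_pf = 0)
  traj0 <- simulate_nh_trajectory(p0, 200)
  expect_true(all(traj0$nh_mm == p0$nh_baseline_mm))
})

test_that("per-step drop depths average to the profile mean", {
  p <- gait_profile(n_steps = 60, nd_mean_mm = 5.0, nd_sd_mm = 0.8,
                    seed = 42)
  traj <- simulate_nh_trajectory(p, 200)
  se <- 0.8 / sqrt(60)
  expect_lt(abs(mean(traj$truth$nd_true_mm) - 5.0), 3 * se)
})

test_that("trajectory rejects invalid sampling setups", {
  expect_error(gait_profile(cadence_hz = 0), "invalid profile")
  expect_error(gait_profile(cadence_hz = -1), "invalid profile")
  expect_error(simulate_nh_trajectory(quiet_profile(), rate_hz = 1),
               "invalid profile")
})

test_that("elongation map is the stated affine function of the drop", {
  p <- quiet_profile(n_steps = 2, seed = 3)
  p$nd_sd_mm <- 0
  traj <- simulate_nh_trajectory(p, 200)
  base <- p$nh_baseline_mm

  e1 <- nh_to_elongation(traj, ideal_sensor())
  expect_equal(max(e1) - min(e1), 5.0, tolerance = 1e-3)
  # at the exact lowest-height time the identity map is exact
  expect_equal(nh_to_elongation(traj$nh_fun(traj$truth$t_nhl_s),
                                ideal_sensor(), baseline = base),
               c(5, 5), tolerance = 1e-12)

  e08 <- nh_to_elongation(traj, ideal_sensor(geometry_gain = 0.8))
  expect_equal(max(e08), 0.8 * 5.0, tolerance = 1e-3)

  # constant NH -> crosstalk only
  flat <- simulate_nh_trajectory(
    gait_profile(n_steps = 2, nd_mean_mm = 0, nd_sd_mm = 0,
                 noise_nh_mm = 0, noise_cap_pf = 0), 200)
  ec <- nh_to_elongation(flat, sensor_model(crosstalk_mm = 0.5))
  expect_true(max(ec) > 0)    # crosstalk present
  e0 <- nh_to_elongation(flat, ideal_sensor())
  expect_true(all(e0 == 0))
})

test_that("over-strain raises an error instead of clipping", {
  p <- quiet_profile(n_steps = 2)
  p$nd_mean_mm <- 25   # 25 mm drop > 50% of 40 mm rest length
  p$nd_sd_mm <- 0
  traj <- simulate_nh_trajectory(p, 200)
  expect_error(nh_to_elongation(traj, ideal_sensor()), "over-strain")
})

test_that("capacitance output is quantized to the resolution step", {
  s <- ideal_sensor()
  cap0 <- elongation_to_capacitance(rep(0, 10), s)
  expect_equal(cap0$capacitance_pF,
               rep(round(100 / 0.13) * 0.13, 10))

  # linear map before quantization: 5 mm at 0.5 mm/pF is 10 pF
  s5 <- ideal_sensor(slope_mm_per_pf = 0.5, quant_pf = 1e-9)
  c5 <- elongation_to_capacitance(c(0, 5), s5)
  expect_equal(diff(c5$capacitance_pF), 10, tolerance = 1e-5)

  # every noiseless sample is an integer multiple of 0.13 pF
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 5), 200)
  cap <- elongation_to_capacitance(nh_to_elongation(traj, ideal_sensor()),
                                   ideal_sensor())
  mult <- cap$capacitance_pF / 0.13
  expect_true(all(abs(mult - round(mult)) < 1e-9))
})

test_that("rendered frames carry gray-coded sample numbers", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 3), 200)
  mf <- render_marker_frames(traj)
  first <- mf[mf$frame == 0, ]
  expect_true(all(first$sync_word == 0))   # gray(0) is all-zero
  expect_true(all(mf$fiducial_ok))
  # word of frame f encodes the nearest strain sample index
  per <- mf[!duplicated(mf$frame), ]
  idx <- gray_decode_int(per$sync_word)
  expect_equal(idx, round(per$t_s * 200))
})

test_that("noiseless marker pixels reproduce the height trajectory", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 3), 200)
  lay <- marker_layout()
  mf <- render_marker_frames(traj, lay)
  nav <- mf[mf$marker_id == "NAV", ]
  nh_dec <- traj$profile$nh_baseline_mm -
    (nav$y_px - lay$nav_px[2]) * lay$mm_per_px
  expect_equal(nh_dec, traj$nh_fun(nav$t_s), tolerance = 1e-9)
})

test_that("a 70 s recording stays within the 16-bit sync range", {
  # 70 s at 200 Hz: last sample index 13999 < 65536
  expect_equal(70 * 200 - 1, 13999)
  p <- gait_profile(n_steps = 64, cadence_hz = 0.93)  # ~70 s trial
  traj <- simulate_nh_trajectory(p, 200)
  mf <- render_marker_frames(traj)
  expect_lt(max(gray_decode_int(mf$sync_word[!duplicated(mf$frame)])),
            65536)
})

test_that("trial generation is deterministic and bookkeeping-consistent", {
  p <- gait_profile(n_steps = 20, seed = 9)
  t1 <- generate_trial(p)
  t2 <- generate_trial(p)
  expect_identical(t1$strain_series$capacitance_pF,
                   t2$strain_series$capacitance_pF)
  expect_identical(t1$marker_series$y_px, t2$marker_series$y_px)
  expect_identical(t1$truth, t2$truth)

  # ~70 s at the default walking cadence gives 55-75 steps
  dur <- 70
  n70 <- floor((dur - 1 / p$cadence_hz) * p$cadence_hz)
  expect_gte(n70, 55)
  expect_lte(n70, 75)

  # truth event times strictly increasing within and across steps
  ev <- as.matrix(t1$truth[, c("t_hs_s", "t_nhl_s", "t_to_s")])
  expect_true(all(diff(as.vector(t(ev))) > 0))
})

test_that("truth drop matches the elongation change at the true events", {
  # crosstalk 0, gain 1, zero noise: elongation(NHL) - elongation(HS)
  # equals the true drop to within one quantization step
  p <- quiet_profile(n_steps = 30, seed = 11)
  s <- ideal_sensor()
  tr <- generate_trial(p, s)
  model <- default_model(s)
  cal <- apply_calibration(tr$strain_series, model)
  i_hs <- round(tr$truth$t_hs_s * 200) + 1
  i_nhl <- round(tr$truth$t_nhl_s * 200) + 1
  nd_est <- cal$elongation_mm[i_nhl] - cal$elongation_mm[i_hs]
  q_mm <- s$quant_pf * abs(model$slope_mm_per_pf)
  expect_lt(max(abs(nd_est - tr$truth$nd_true_mm)), 2 * q_mm + 1e-6)
})
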