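test_that("segmentation finds every step of a clean trial", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 60), 200)
  st <- segment_steps(traj$nh_mm, 200)
  expect_equal(nrow(st), 60)
  expect_true(all(st$start < st$anchor & st$anchor < st$end))

  expect_error(segment_steps(rep(1, 5000), 200), "cannot segment")
  set.seed(1)
  expect_error(segment_steps(rnorm(5000), 200), "cannot segment")
})

test_that("segmentation tolerates capacitance-level noise", {
  p <- gait_profile(n_steps = 20, noise_nh_mm = 0, noise_cap_pf = 0.26,
                    seed = 13)     # 2 quanta of capacitance noise
  s <- ideal_sensor()
  tr <- generate_trial(p, s)
  cal <- apply_calibration(tr$strain_series, default_model(s))
  st <- segment_steps(cal$elongation_mm, 200)
  expect_gte(nrow(st), 19)
  expect_lte(nrow(st), 21)
})

test_that("video-rule events recover the true drop on clean steps", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 60), 200)
  ev <- detect_mvsa_events(traj$nh_mm, 200)
  m <- match_events_to_truth(ev, traj$truth, traj$t_s)
  expect_true(all(!is.na(m)))
  nds <- nd_from_mvsa(traj$nh_mm, ev)
  expect_lt(max(abs(nds - traj$truth$nd_true_mm[m])), 0.05)
})

test_that("flat steps are skipped, never fabricated", {
  p <- gait_profile(n_steps = 3, nd_mean_mm = 0, nd_sd_mm = 0,
                    noise_nh_mm = 0, noise_cap_pf = 0)
  traj <- simulate_nh_trajectory(p, 200)
  expect_error(detect_mvsa_events(traj$nh_mm, 200))
})

test_that("event ordering holds on every step of a noisy trial", {
  p <- gait_profile(n_steps = 60, seed = 21)   # default noise levels
  tr <- generate_trial(p)
  res <- analyze_trial(tr$strain_series, tr$marker_series,
                       default_model(tr$sensor))
  for (ev in list(res$mvsa_events, res$pbs_events)) {
    expect_true(all(ev$start <= ev$hs_index))
    expect_true(all(ev$hs_index < ev$nhl_index))
    expect_true(all(ev$nhl_index < ev$to_index))
    expect_true(all(ev$to_index <= ev$end))
  }
})

test_that("sensor heel strike finds the dip inside the 10% window", {
  # V-shaped dip centered 3 samples after the anchor
  elong <- rep(1, 100)
  elong[40:56] <- c(8:0, 1:8) / 8
  expect_equal(detect_pbs_hs(elong, mvsa_hs = 45, step_len = 100), 48)
  # flat window: earliest index by the tie-break convention
  expect_equal(detect_pbs_hs(rep(2, 100), mvsa_hs = 50, step_len = 100),
               40)
  # clipping warns
  expect_warning(detect_pbs_hs(elong, mvsa_hs = 5, step_len = 200),
                 "clipped")
})

test_that("sensor heel strike lands within 3 samples of truth", {
  p <- quiet_profile(n_steps = 40, seed = 31)
  tr <- generate_trial(p, sensor_model())   # default crosstalk
  model <- default_model(tr$sensor)
  res <- analyze_trial(tr$strain_series, tr$marker_series, model)
  m <- match_events_to_truth(res$pbs_events, tr$truth,
                             tr$strain_series$t_s)
  err <- tr$strain_series$t_s[res$pbs_events$hs_index] -
    tr$truth$t_hs_s[m]
  expect_lt(max(abs(err)), 3.5 / 200)
})

test_that("sensor-side lowest height is the strain argmax, earliest on ties", {
  x <- c(0, 1, 3, 2, 3, 1, 0)
  expect_equal(detect_pbs_nhl(x, 1, 7), 3)
  single <- c(0, 1, 4, 1, 0)
  expect_equal(detect_pbs_nhl(single, 1, 5), 3)
  expect_error(detect_pbs_nhl(x, 5, 3), "empty")

  # matches the true lowest-height time on a clean trial
  p <- quiet_profile(n_steps = 30, seed = 32)
  tr <- generate_trial(p, ideal_sensor())
  cal <- apply_calibration(tr$strain_series, default_model(tr$sensor))
  i_hs <- round(tr$truth$t_hs_s * 200) + 1
  half <- round(0.5 * 200 / p$cadence_hz)
  for (k in c(1, 15, 30)) {
    nhl <- detect_pbs_nhl(cal$elongation_mm, i_hs[k],
                          min(length(cal$elongation_mm), i_hs[k] + half))
    expect_lt(abs(nhl - (round(tr$truth$t_nhl_s[k] * 200) + 1)), 4)
  }
})

test_that("standalone in-shoe mode recovers the drop without a reference", {
  p <- quiet_profile(n_steps = 40, seed = 33)
  tr <- generate_trial(p, ideal_sensor())
  cal <- apply_calibration(tr$strain_series, default_model(tr$sensor))
  ev <- detect_inshoe_events(cal$elongation_mm, 200)
  expect_equal(attr(ev, "mode"), "standalone")
  m <- match_events_to_truth(ev, tr$truth, tr$strain_series$t_s)
  nds <- nd_from_pbs(cal$elongation_mm, ev)
  expect_lt(max(abs(nds - tr$truth$nd_true_mm[m])), 0.2)

  set.seed(2)
  expect_error(detect_inshoe_events(rnorm(4000), 200), "cannot segment")
})

test_that("standalone and reference-anchored heel strikes agree", {
  p <- quiet_profile(n_steps = 40, seed = 34)
  tr <- generate_trial(p, sensor_model())   # default crosstalk
  model <- default_model(tr$sensor)
  res <- analyze_trial(tr$strain_series, tr$marker_series, model)
  cal <- apply_calibration(tr$strain_series, model)
  ev_sa <- detect_inshoe_events(cal$elongation_mm, 200)
  m_sa <- match_events_to_truth(ev_sa, tr$truth, tr$strain_series$t_s)
  m_rf <- match_events_to_truth(res$pbs_events, tr$truth,
                                tr$strain_series$t_s)
  common <- intersect(m_sa, m_rf)
  d <- ev_sa$hs_index[match(common, m_sa)] -
    res$pbs_events$hs_index[match(common, m_rf)]
  expect_lte(median(abs(d)), 3)
})
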