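test_that("gray bit vectors match the xor definition", {
  expect_equal(gray_encode(0), rep(0L, 16))
  expect_equal(gray_encode(1)[1:4], c(1L, 0L, 0L, 0L))   # LSB-first ...0001
  expect_equal(gray_encode(2)[1:4], c(1L, 1L, 0L, 0L))   # ...0011
  expect_equal(gray_decode(rep(0L, 16)), 0)
  expect_equal(gray_decode(c(1L, 1L, 0L, 0L)), 2)
  expect_error(gray_encode(65536))
  expect_error(gray_encode(-1))
  # round-trip through the bit-vector interface on a sample of words
  for (n in c(0, 1, 2, 255, 4096, 65535))
    expect_equal(gray_decode(gray_encode(n)), n)
})

test_that("gray code round-trips and changes one bit per increment", {
  n <- 0:65535
  g <- gray_encode_int(n)
  expect_identical(gray_decode_int(g), n)
  # popcount of consecutive xors is exactly 1
  x <- bitwXor(g[-1], g[-length(g)])
  pc <- integer(length(x))
  for (b in 0:15) pc <- pc + bitwAnd(bitwShiftR(x, b), 1L)
  expect_true(all(pc == 1L))
})

test_that("frame decoding unwraps, flags glitches, needs two valid frames", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 5), 200)
  mf <- render_marker_frames(traj)
  sm <- decode_frames(mf, n_samples = length(traj$t_s))
  expect_true(all(sm$valid))
  expect_true(all(diff(sm$sample_index) > 0))
  expect_equal(sm$sample_index, round(sm$t_s * 200))

  # corrupt one word mid-stream: exactly that frame invalidated
  mf2 <- mf
  bad <- mf2$frame == 100
  mf2$sync_word[bad] <- bitwXor(mf2$sync_word[bad][1], 16384L)
  sm2 <- decode_frames(mf2, n_samples = length(traj$t_s))
  expect_false(sm2$valid[sm2$frame == 100])
  expect_true(all(sm2$valid[sm2$frame != 100]))
  expect_equal(sm2$sample_index[sm2$frame != 100],
               sm$sample_index[sm$frame != 100])

  # all fiducials off: cannot sync
  mf3 <- mf
  mf3$fiducial_ok <- FALSE
  expect_error(decode_frames(mf3), "cannot sync")
})

test_that("sample numbers unwrap across the 16-bit boundary", {
  # 6-minute walk: sample indices exceed 65535 and must unwrap
  p <- quiet_profile(n_steps = 340L, seed = 5)
  traj <- simulate_nh_trajectory(p, 200)
  expect_gt(length(traj$t_s), 65536)
  mf <- render_marker_frames(traj)
  sm <- decode_frames(mf, n_samples = length(traj$t_s))
  expect_true(all(sm$valid))
  expect_equal(sm$sample_index, round(sm$t_s * 200))
  expect_gt(max(sm$sample_index), 65535)
})

test_that("upsampling is exact on lines and at frame-aligned samples", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 5), 200)
  n <- length(traj$t_s)
  mf <- render_marker_frames(traj)
  sm <- decode_frames(mf, n_samples = n)

  # linear interpolation is exact on a signal linear in the sample index
  ramp_i <- 2 + 3 * sm$sample_index
  up_i <- upsample_to_strain_timeline(ramp_i, sm, n, refine = FALSE)
  xout <- seq_len(n) - 1
  in_i <- !is.na(up_i)
  expect_equal(up_i[in_i], 2 + 3 * xout[in_i], tolerance = 1e-9)

  # a ramp in time survives the clock-refined path to well under a sample
  ramp <- 2 + 3 * sm$t_s
  up <- upsample_to_strain_timeline(ramp, sm, n)
  inside <- !is.na(up)
  t200 <- (seq_len(n) - 1) / 200
  expect_equal(up[inside], 2 + 3 * t200[inside], tolerance = 1e-3)

  # without clock refinement the decoded indices are the knots, and
  # frame-aligned strain samples reproduce the frame values bit for bit
  vals <- sin(sm$t_s)
  up2 <- upsample_to_strain_timeline(vals, sm, n, refine = FALSE)
  aligned <- sm$sample_index + 1
  expect_identical(up2[aligned], vals)

  # no extrapolation beyond the last frame
  expect_true(all(is.na(up[(max(sm$sample_index) + 2):n])) ||
                max(sm$sample_index) + 2 > n)
})

test_that("a 5 Hz sinusoid survives upsampling to within 1% amplitude", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 5), 200)
  n <- length(traj$t_s)
  mf <- render_marker_frames(traj)
  sm <- decode_frames(mf, n_samples = n)
  vals <- sin(2 * pi * 5 * sm$t_s)
  up <- upsample_to_strain_timeline(vals, sm, n)
  t200 <- (seq_len(n) - 1) / 200
  inside <- !is.na(up)
  expect_lt(max(abs(up[inside] - sin(2 * pi * 5 * t200[inside]))), 0.01)
})

test_that("event times transfer between timelines to sub-sample accuracy", {
  p <- gait_profile(n_steps = 64, noise_nh_mm = 0, noise_cap_pf = 0,
                    seed = 8)
  traj <- simulate_nh_trajectory(p, 200)
  mf <- render_marker_frames(traj)
  sm <- decode_frames(mf, n_samples = length(traj$t_s))
  ev_t <- c(traj$truth$t_hs_s, traj$truth$t_nhl_s, traj$truth$t_to_s)
  got <- transfer_time(ev_t, sm)
  expect_lt(max(abs(got - ev_t)), 0.0025)   # half a 200 Hz sample
})
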