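test_that("local frame puts B at the origin and A on +x", {
  mk <- data.frame(marker_id = c("B", "A", "M"),
                   x_px = c(5, 10, 7), y_px = c(5, 5, 3))
  loc <- to_local_frame(mk)
  expect_equal(loc$x_local[loc$marker_id == "B"], 0)
  expect_equal(loc$y_local[loc$marker_id == "B"], 0)
  expect_equal(loc$x_local[loc$marker_id == "A"], 5)
  expect_equal(loc$y_local[loc$marker_id == "A"], 0, tolerance = 1e-9)
  expect_equal(loc$x_local[loc$marker_id == "M"], 2)
  expect_equal(loc$y_local[loc$marker_id == "M"], -2)

  # already axis-aligned with B at origin: identity
  mk2 <- data.frame(marker_id = c("B", "A", "M"),
                    x_px = c(0, 8, 3), y_px = c(0, 0, 4))
  loc2 <- to_local_frame(mk2)
  expect_equal(loc2$x_local, mk2$x_px)
  expect_equal(loc2$y_local, mk2$y_px)

  expect_error(to_local_frame(data.frame(marker_id = c("A", "B"),
                                         x_px = c(1, 1), y_px = c(2, 2))),
               "degenerate")
})

test_that("local coordinates are invariant under global rigid motion", {
  mk <- data.frame(marker_id = c("B", "A", "M", "N"),
                   x_px = c(5, 10, 7, 2), y_px = c(5, 5, 3, 9))
  base <- to_local_frame(mk)
  for (th in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy <- as.matrix(mk[, c("x_px", "y_px")]) %*% t(R)
    rot <- data.frame(marker_id = mk$marker_id,
                      x_px = xy[, 1] + 11, y_px = xy[, 2] - 4)
    loc <- to_local_frame(rot)
    expect_equal(loc$x_local, base$x_local, tolerance = 1e-9)
    expect_equal(loc$y_local, base$y_local, tolerance = 1e-9)
    # isometry: pairwise distances preserved
    d0 <- dist(as.matrix(mk[, c("x_px", "y_px")]))
    d1 <- dist(cbind(loc$x_local, loc$y_local))
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  }
})

test_that("displacement clouds reflect marker motion in the local frame", {
  traj <- simulate_nh_trajectory(quiet_profile(n_steps = 10), 200)
  mf <- render_marker_frames(traj)
  # reference markers are static: their clouds are all zeros -> isotropic
  # guard would trigger, so test the navicular marker
  cl <- displacement_cloud(mf, "NAV", mm_per_px = 0.2)
  expect_equal(mean(cl$points[, 1]), 0, tolerance = 1e-9)
  expect_equal(mean(cl$points[, 2]), 0, tolerance = 1e-9)
  # purely vertical motion: x spread is zero
  expect_lt(max(abs(cl$points[, 1])), 1e-9)
  # vertical extent matches the true drop range within 5%
  extent <- diff(range(cl$points[, 2]))
  expect_lt(abs(extent - max(traj$truth$nd_true_mm)) /
              max(traj$truth$nd_true_mm), 0.05)

  expect_error(displacement_cloud(mf, "NOPE"), "fewer than 2 frames")
})

test_that("major axis recovers known cloud orientations", {
  expect_equal(major_axis(point_cloud(rbind(c(0, -1), c(0, 1))))$angle_deg,
               90)
  expect_equal(major_axis(point_cloud(rbind(c(-1, -1), c(1, 1),
                                            c(2, 2))))$angle_deg, 45)
  g <- gaussian_cloud(500, 30, sd_major = 5, sd_minor = 1, seed = 4)
  expect_lt(abs(major_axis(g)$angle_deg - 30), 3)
  # exactly isotropic cloud (regular polygon) refuses
  th <- 2 * pi * (0:7) / 8
  iso <- point_cloud(cbind(cos(th), sin(th)))
  expect_error(major_axis(iso), "isotropic")
})

test_that("major-axis angle is equivariant under cloud rotation", {
  g <- gaussian_cloud(500, 20, sd_major = 5, sd_minor = 1, seed = 10)
  a0 <- major_axis(g)$angle_deg
  for (th_deg in c(35, 90, 140)) {
    th <- th_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    gr <- point_cloud(g$points %*% t(R))
    expect_equal(major_axis(gr)$angle_deg %% 180, (a0 + th_deg) %% 180,
                 tolerance = 1e-6)
  }
})

test_that("inter-axis angle reproduces constructed geometries", {
  c30 <- gaussian_cloud(800, 30, seed = 1)
  c150 <- gaussian_cloud(800, 150, seed = 2)
  expect_equal(axis_angle_between(c30, c30), 0)
  expect_lt(abs(axis_angle_between(c30, c150) - 120), 2)
  expect_equal(axis_angle_between(c30, c150),
               axis_angle_between(c150, c30))
  c0 <- gaussian_cloud(800, 0, seed = 3)
  c90 <- gaussian_cloud(800, 90, seed = 4)
  expect_lt(abs(axis_angle_between(c0, c90) - 90), 2)
})

test_that("attachment scoring prefers perpendicular upper-site motion", {
  up_perp <- point_cloud(rbind(c(0, -2), c(0, 2)))   # axis 90 deg
  up_par <- point_cloud(rbind(c(-2, 0), c(2, 0)))    # axis 0 deg
  low <- gaussian_cloud(100, 60, seed = 5)
  s_perp <- score_attachment_pair(up_perp, low, sensor_line = 0)
  s_par <- score_attachment_pair(up_par, low, sensor_line = 0)
  expect_equal(s_perp$score, 0, tolerance = 1e-9)
  expect_equal(s_par$score, 1)

  # constructed perpendicular site ranks first in a candidate grid
  pairs <- list(
    list(upper = gaussian_cloud(300, 85, seed = 7), lower = low,
         sensor_line = 0),
    list(upper = up_perp, lower = low, sensor_line = 0),
    list(upper = gaussian_cloud(300, 30, seed = 8), lower = low,
         sensor_line = 0),
    list(upper = up_par, lower = low, sensor_line = 0))
  rk <- rank_attachment_pairs(pairs)
  expect_equal(rk$pair[1], 2)
  # direction-vector form agrees with angle form
  s_vec <- score_attachment_pair(up_perp, low, sensor_line = c(1, 0))
  expect_equal(s_vec$score, s_perp$score)
})
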