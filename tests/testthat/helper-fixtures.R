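# Shared fixture builders. All fixtures are generated in code; "quiet"
# means zero measurement noise (crosstalk is controlled separately because
# it is signal, not noise).

quiet_profile <- function(n_steps = 60L, seed = 42L, ...) {
  gait_profile(n_steps = n_steps, nd_mean_mm = 5.0, nd_sd_mm = 0.8,
               noise_nh_mm = 0, noise_cap_pf = 0, seed = seed, ...)
}

ideal_sensor <- function(...) {
  do.call(sensor_model,
          utils::modifyList(list(geometry_gain = 1, crosstalk_mm = 0),
                            list(...)))
}

default_model <- function(sensor = sensor_model()) {
  fit_calibration(simulate_calibration_sweep(sensor))
}

# anisotropic Gaussian cloud with a known major-axis angle (degrees)
gaussian_cloud <- function(n, angle_deg, sd_major = 5, sd_minor = 1,
                           seed = 1) {
  set.seed(seed)
  th <- angle_deg * pi / 180
  u <- rnorm(n, 0, sd_major)
  v <- rnorm(n, 0, sd_minor)
  point_cloud(cbind(u * cos(th) - v * sin(th),
                    u * sin(th) + v * cos(th)))
}
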