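#' Gait profile for the synthetic trial generator
#'
#' Parameters of the simulated walking trial. Defaults describe a healthy
#' adult walking at preferred treadmill speed (about 5 km/h): stride rate
#' 0.93 Hz (so a 70 s recording holds about 65 steps of one foot), mean
#' navicular drop 5.0 mm with 0.8 mm stride-to-stride SD, navicular height
#' baseline 40 mm, stance occupying 62% of the stride with the lowest
#' navicular height halfway through stance.
#'
#' @param n_steps number of strides to generate (>= 1).
#' @param cadence_hz stride rate of one foot, strides per second.
#' @param nd_mean_mm true mean navicular drop, mm (>= 0).
#' @param nd_sd_mm stride-to-stride SD of the true drop, mm (>= 0).
#' @param nh_baseline_mm navicular height at heel strike, mm.
#' @param stance_fraction fraction of the stride spent in stance (0-1).
#' @param nhl_fraction_of_stance fraction of stance at which the lowest
#'   navicular height occurs (0-1).
#' @param noise_nh_mm SD of additive marker measurement noise, mm.
#' @param noise_cap_pf SD of additive capacitance measurement noise, pF.
#' @param seed RNG seed; the whole trial is deterministic given the seed.
#' @return an object of class \code{gait_profile}.
#' @export
gait_profile <- function(n_steps = 65L, cadence_hz = 0.93,
                         nd_mean_mm = 5.0, nd_sd_mm = 0.8,
                         nh_baseline_mm = 40, stance_fraction = 0.62,
                         nhl_fraction_of_stance = 0.5,
                         noise_nh_mm = 0.1, noise_cap_pf = 0.13,
                         seed = 1L) {
  if (n_steps < 1L) stop("invalid profile: n_steps must be >= 1")
  if (!is.finite(cadence_hz) || cadence_hz <= 0)
    stop("invalid profile: cadence_hz must be positive")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("invalid profile: stance_fraction must be in (0, 1)")
  if (nhl_fraction_of_stance <= 0 || nhl_fraction_of_stance >= 1)
    stop("invalid profile: nhl_fraction_of_stance must be in (0, 1)")
  if (nd_mean_mm < 0 || nd_sd_mm < 0 || noise_nh_mm < 0 || noise_cap_pf < 0)
    stop("invalid profile: nd_mean_mm and all SDs must be >= 0")
  structure(list(n_steps = as.integer(n_steps), cadence_hz = cadence_hz,
                 nd_mean_mm = nd_mean_mm, nd_sd_mm = nd_sd_mm,
                 nh_baseline_mm = nh_baseline_mm,
                 stance_fraction = stance_fraction,
                 nhl_fraction_of_stance = nhl_fraction_of_stance,
                 noise_nh_mm = noise_nh_mm, noise_cap_pf = noise_cap_pf,
                 seed = as.integer(seed)),
            class = "gait_profile")
}

#' Capacitive strain-sensor transduction model
#'
#' Linear strain-to-capacitance transduction with quantization, matching the
#' modeled hardware: 0.13 pF capacitance resolution, 200 Hz sampling, and a
#' strainable section that tolerates at most 50% relative strain (straining
#' further damages the material, so the simulator refuses rather than
#' clips). The default 40 mm rest length makes a 20 mm calibration-sweep
#' extension equal 50% strain. \code{geometry_gain} maps navicular-height
#' drop to sensor elongation (1 = ideal sagittal alignment);
#' \code{crosstalk_mm} is the amplitude of a smooth stride-locked
#' non-sagittal (frontal-plane) elongation component that contaminates the
#' sensor but is invisible to the single-camera video reference.
#'
#' @param rest_length_mm rest length of the strainable section, mm (> 0).
#' @param max_strain_frac maximal tolerated relative strain (0-1].
#' @param slope_mm_per_pf transduction slope, mm of elongation per pF.
#' @param intercept_pf capacitance at zero elongation, pF.
#' @param quant_pf quantization step of the acquisition chain, pF (> 0).
#' @param sample_rate_hz sensor sampling rate, Hz.
#' @param geometry_gain dimensionless navicular-drop-to-elongation gain.
#' @param crosstalk_mm amplitude of the frontal-plane crosstalk component, mm.
#' @return an object of class \code{sensor_model}.
#' @export
sensor_model <- function(rest_length_mm = 40, max_strain_frac = 0.5,
                         slope_mm_per_pf = 0.1, intercept_pf = 100,
                         quant_pf = 0.13, sample_rate_hz = 200,
                         geometry_gain = 1, crosstalk_mm = 0.5) {
  if (rest_length_mm <= 0) stop("rest_length_mm must be > 0")
  if (quant_pf <= 0) stop("quant_pf must be > 0")
  if (max_strain_frac <= 0 || max_strain_frac > 1)
    stop("max_strain_frac must be in (0, 1]")
  if (!is.finite(slope_mm_per_pf) || slope_mm_per_pf == 0)
    stop("slope_mm_per_pf must be finite and nonzero")
  if (crosstalk_mm < 0) stop("crosstalk_mm must be >= 0")
  structure(list(rest_length_mm = rest_length_mm,
                 max_strain_frac = max_strain_frac,
                 slope_mm_per_pf = slope_mm_per_pf,
                 intercept_pf = intercept_pf, quant_pf = quant_pf,
                 sample_rate_hz = sample_rate_hz,
                 geometry_gain = geometry_gain,
                 crosstalk_mm = crosstalk_mm),
            class = "sensor_model")
}

#' Marker/pixel geometry of the simulated camera view
#'
#' Reference markers A (front foot) and B (calcaneus) and the navicular
#' marker, in pixel coordinates with the image convention (y grows
#' downward, so a dropping navicular moves to larger y).
#'
#' @param mm_per_px metric scale of the image, mm per pixel.
#' @param a_px,b_px,nav_px length-2 pixel positions (x, y) of markers A, B
#'   and of the navicular marker at baseline height.
#' @return a list of class \code{marker_layout}.
#' @export
marker_layout <- function(mm_per_px = 0.2, a_px = c(600, 400),
                          b_px = c(100, 400), nav_px = c(350, 300)) {
  structure(list(mm_per_px = mm_per_px, a_px = a_px, b_px = b_px,
                 nav_px = nav_px),
            class = "marker_layout")
}

# Raised-cosine stride template for the navicular height, evaluated at
# arbitrary times. Baseline during swing; smooth (C^1) descent from HS to a
# per-stride minimum of depth d_k at nhl_fraction_of_stance of stance, then
# smooth recovery to baseline at toe off. Lead-in/out of half a stride of
# quiet standing pads the trial at both ends.
nh_template_fun <- function(profile, depths) {
  T_stride <- 1 / profile$cadence_hz
  lead <- 0.5 * T_stride
  t_stance <- profile$stance_fraction * T_stride
  t_nhl <- profile$nhl_fraction_of_stance * t_stance
  base <- profile$nh_baseline_mm
  n <- profile$n_steps
  function(t) {
    tau <- t - lead
    k <- floor(tau / T_stride) + 1
    inside <- k >= 1 & k <= n & tau >= 0
    loc <- tau - (k - 1) * T_stride
    w <- numeric(length(t))
    desc <- inside & loc < t_nhl
    reco <- inside & loc >= t_nhl & loc < t_stance
    w[desc] <- 0.5 * (1 - cos(pi * loc[desc] / t_nhl))
    w[reco] <- 0.5 * (1 + cos(pi * (loc[reco] - t_nhl) / (t_stance - t_nhl)))
    d <- numeric(length(t))
    d[inside] <- depths[k[inside]]
    base - d * w
  }
}

#' Simulate a ground-truth navicular-height trajectory
#'
#' Generates the continuous navicular-height (NH) waveform of a walking
#' trial sampled at \code{rate_hz}, together with the per-step truth record
#' (true heel-strike, lowest-navicular-height and toe-off times and the true
#' per-step drop). Per-step drop depths are drawn from
#' Normal(\code{nd_mean_mm}, \code{nd_sd_mm}) truncated at zero; the true
#' drop of step k equals its depth exactly. Deterministic given
#' \code{profile$seed}.
#'
#' @param profile a \code{\link{gait_profile}}.
#' @param rate_hz sampling rate, must exceed twice the cadence.
#' @return a list of class \code{nh_trajectory} with elements \code{t_s},
#'   \code{nh_mm}, \code{truth} (data frame \code{step, t_hs_s, t_nhl_s,
#'   t_to_s, nd_true_mm}), \code{rate_hz}, \code{profile} and \code{nh_fun}
#'   (the continuous template, for exact evaluation at camera frame times).
#' @export
simulate_nh_trajectory <- function(profile, rate_hz = 200) {
  stopifnot(inherits(profile, "gait_profile"))
  if (!is.finite(rate_hz) || rate_hz <= 2 * profile$cadence_hz)
    stop("invalid profile: rate_hz must exceed twice the cadence")
  T_stride <- 1 / profile$cadence_hz
  lead <- 0.5 * T_stride
  duration <- 2 * lead + profile$n_steps * T_stride
  set.seed(profile$seed)
  depths <- pmax(0, stats::rnorm(profile$n_steps, profile$nd_mean_mm,
                                 profile$nd_sd_mm))
  nh_fun <- nh_template_fun(profile, depths)
  n_samp <- floor(duration * rate_hz) + 1L
  t_s <- (seq_len(n_samp) - 1L) / rate_hz
  t_hs <- lead + (seq_len(profile$n_steps) - 1L) * T_stride
  truth <- data.frame(
    step = seq_len(profile$n_steps),
    t_hs_s = t_hs,
    t_nhl_s = t_hs + profile$nhl_fraction_of_stance *
      profile$stance_fraction * T_stride,
    t_to_s = t_hs + profile$stance_fraction * T_stride,
    nd_true_mm = depths)
  structure(list(t_s = t_s, nh_mm = nh_fun(t_s), truth = truth,
                 rate_hz = rate_hz, profile = profile, nh_fun = nh_fun),
            class = "nh_trajectory")
}

# Stride-locked crosstalk waveform, exactly zero at every heel strike.
# Piecewise raised-cosine (C^1): rises over the first 45% of the stride
# (mid-stance frontal-plane pronation), plateaus through swing, and falls
# steeply over the final 10% -- the characteristic strain drop into heel
# strike seen on real sensor records, which is what makes the sensor-side
# heel strike localizable. Per-stride amplitudes are scaled uniform in
# [0.5, 1.5] of the nominal amplitude: frontal-plane motion varies stride
# to stride.
crosstalk_shape <- function(phi, rise = 0.45, fall = 0.90) {
  s <- numeric(length(phi))
  a <- phi < rise
  b <- phi >= rise & phi < fall
  c <- phi >= fall & phi <= 1
  s[a] <- 0.5 * (1 - cos(pi * phi[a] / rise))
  s[b] <- 1
  s[c] <- 0.5 * (1 + cos(pi * (phi[c] - fall) / (1 - fall)))
  s
}

crosstalk_fun <- function(amp_mm, truth, cadence_hz, seed) {
  T_stride <- 1 / cadence_hz
  set.seed(seed)
  # virtual stride 0 at nominal amplitude covers the lead-in: the subject
  # is already walking when acquisition starts, so the first heel strike
  # carries the same pre-HS strain descent as every other one
  amps <- c(amp_mm, amp_mm * stats::runif(nrow(truth), 0.5, 1.5))
  t0 <- truth$t_hs_s[1] - T_stride
  n_str <- length(amps)
  function(t) {
    k <- floor((t - t0) / T_stride) + 1
    inside <- k >= 1 & k <= n_str & t >= t0
    phi <- (t - t0) / T_stride - (k - 1)
    out <- numeric(length(t))
    out[inside] <- amps[k[inside]] * crosstalk_shape(phi[inside])
    out
  }
}

#' Map a navicular-height series to sensor elongation
#'
#' Elongation = \code{geometry_gain * (baseline - NH)} plus, when
#' \code{sensor$crosstalk_mm > 0}, a smooth stride-locked frontal-plane
#' crosstalk component (zero exactly at heel strike). With zero crosstalk
#' and unit gain the elongation change from heel strike to lowest navicular
#' height equals the true drop exactly. Elongations beyond
#' \code{max_strain_frac * rest_length_mm} would damage the sensor material
#' and raise an over-strain error instead of being clipped.
#'
#' @param nh an \code{nh_trajectory} from \code{\link{simulate_nh_trajectory}},
#'   or a plain numeric NH vector (crosstalk then requires \code{t_s} and
#'   \code{truth}).
#' @param sensor a \code{\link{sensor_model}}.
#' @param baseline navicular-height baseline, mm; taken from the trajectory's
#'   profile when omitted.
#' @param t_s,truth,cadence_hz stride timing, needed only for the crosstalk
#'   term when \code{nh} is a plain vector.
#' @param seed RNG seed for the per-stride crosstalk amplitudes.
#' @return numeric elongation series, mm (same length as the NH series).
#' @export
nh_to_elongation <- function(nh, sensor, baseline = NULL, t_s = NULL,
                             truth = NULL, cadence_hz = NULL, seed = NULL) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (inherits(nh, "nh_trajectory")) {
    t_s <- nh$t_s
    truth <- nh$truth
    cadence_hz <- nh$profile$cadence_hz
    if (is.null(baseline)) baseline <- nh$profile$nh_baseline_mm
    if (is.null(seed)) seed <- nh$profile$seed + 3L
    nh <- nh$nh_mm
  }
  if (is.null(baseline)) stop("baseline required for plain NH input")
  elong <- sensor$geometry_gain * (baseline - nh)
  if (sensor$crosstalk_mm > 0) {
    if (is.null(t_s) || is.null(truth) || is.null(cadence_hz))
      stop("crosstalk requires stride timing (t_s, truth, cadence_hz)")
    if (is.null(seed)) seed <- 0L
    ct <- crosstalk_fun(sensor$crosstalk_mm, truth, cadence_hz, seed)
    elong <- elong + ct(t_s)
  }
  limit <- sensor$max_strain_frac * sensor$rest_length_mm
  if (any(elong > limit))
    stop(sprintf(paste0("over-strain: elongation %.2f mm exceeds %.0f%% of ",
                        "the %.0f mm rest length; the material would be ",
                        "damaged"),
                 max(elong), 100 * sensor$max_strain_frac,
                 sensor$rest_length_mm))
  if (any(elong < -1e-9))
    stop("negative elongation: NH above baseline is not representable")
  pmax(elong, 0)
}

#' Convert an elongation series to a quantized capacitance record
#'
#' Applies the inverse transduction \code{C = intercept_pf +
#' elongation / slope_mm_per_pf}, adds Gaussian measurement noise, and
#' quantizes to the nearest multiple of \code{quant_pf} (0.13 pF for the
#' modeled acquisition chain).
#'
#' @param elong numeric elongation series, mm.
#' @param sensor a \code{\link{sensor_model}}.
#' @param t_s sample times; defaults to a uniform grid at the sensor rate.
#' @param noise_sd_pf SD of additive capacitance noise, pF.
#' @param seed RNG seed for the noise.
#' @return a \code{\link{strain_series}} with a \code{capacitance_pF} column.
#' @export
elongation_to_capacitance <- function(elong, sensor, t_s = NULL,
                                      noise_sd_pf = 0, seed = NULL) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (is.null(t_s))
    t_s <- (seq_along(elong) - 1L) / sensor$sample_rate_hz
  cap <- sensor$intercept_pf + elong / sensor$slope_mm_per_pf
  if (noise_sd_pf > 0) {
    if (!is.null(seed)) set.seed(seed)
    cap <- cap + stats::rnorm(length(cap), 0, noise_sd_pf)
  }
  cap <- round(cap / sensor$quant_pf) * sensor$quant_pf
  strain_series(t_s, capacitance_pF = cap, rate_hz = sensor$sample_rate_hz)
}

#' Render camera marker frames from a navicular-height trajectory
#'
#' Produces the 114 Hz marker-frame stream a video reference system would
#' record: per frame, pixel positions of the reference markers A and B and
#' of the navicular marker (height encoded on the image y axis, which grows
#' downward, at the layout's mm-per-px scale, plus Gaussian pixel noise),
#' the 16-bit gray-code sync word of the strain sample nearest the frame
#' time, and two fiducial bits set on. Sample indices beyond the 16-bit
#' range are encoded modulo 2^16 (the decoder unwraps by nearest
#' continuation).
#'
#' @param nh an \code{nh_trajectory}.
#' @param layout a \code{\link{marker_layout}}.
#' @param frame_rate_hz camera frame rate, Hz.
#' @param sync_origin strain-sample index (0-based) concurrent with time 0.
#' @param noise_px SD of additive pixel noise applied to every marker.
#' @param seed RNG seed for the pixel noise.
#' @param strain_rate_hz strain-stream rate used to form sync words.
#' @return a \code{\link{marker_frames}} object.
#' @export
render_marker_frames <- function(nh, layout = marker_layout(),
                                 frame_rate_hz = 114, sync_origin = 0L,
                                 noise_px = 0, seed = NULL,
                                 strain_rate_hz = 200) {
  stopifnot(inherits(nh, "nh_trajectory"), inherits(layout, "marker_layout"))
  if (sync_origin < 0) stop("sync_origin must be a valid sample index")
  duration <- nh$t_s[length(nh$t_s)]
  n_frames <- floor(duration * frame_rate_hz) + 1L
  f <- seq_len(n_frames) - 1L
  tf <- f / frame_rate_hz
  idx <- (round(tf * strain_rate_hz) + sync_origin) %% 65536
  words <- gray_encode_int(as.integer(idx))
  nh_f <- nh$nh_fun(tf)
  base <- nh$profile$nh_baseline_mm
  nav_y <- layout$nav_px[2] + (base - nh_f) / layout$mm_per_px
  xs <- c(rep(layout$a_px[1], n_frames), rep(layout$b_px[1], n_frames),
          rep(layout$nav_px[1], n_frames))
  ys <- c(rep(layout$a_px[2], n_frames), rep(layout$b_px[2], n_frames),
          nav_y)
  if (noise_px > 0) {
    if (!is.null(seed)) set.seed(seed)
    xs <- xs + stats::rnorm(length(xs), 0, noise_px)
    ys <- ys + stats::rnorm(length(ys), 0, noise_px)
  }
  marker_frames(frame = rep(f, 3L), t_s = rep(tf, 3L),
                marker_id = rep(c("A", "B", "NAV"), each = n_frames),
                x_px = xs, y_px = ys,
                sync_word = rep(words, 3L),
                fiducial_ok = rep(TRUE, 3L * n_frames),
                rate_hz = frame_rate_hz)
}

#' Generate a complete synthetic trial with ground truth
#'
#' Composes the trajectory, transduction and camera models into the two
#' acquisition streams the pipeline consumes, plus the truth record.
#' Deterministic given \code{profile$seed} (noise and crosstalk draws use
#' fixed offsets of that seed).
#'
#' @param profile a \code{\link{gait_profile}}.
#' @param sensor a \code{\link{sensor_model}}.
#' @param layout a \code{\link{marker_layout}}.
#' @return a list of class \code{simulated_trial}: \code{truth},
#'   \code{strain_series}, \code{marker_series}, \code{elongation_true_mm},
#'   \code{nh}, \code{profile}, \code{sensor}, \code{layout}.
#' @export
generate_trial <- function(profile = gait_profile(),
                           sensor = sensor_model(),
                           layout = marker_layout()) {
  nh <- simulate_nh_trajectory(profile, sensor$sample_rate_hz)
  elong <- nh_to_elongation(nh, sensor)
  strain <- elongation_to_capacitance(elong, sensor, t_s = nh$t_s,
                                      noise_sd_pf = profile$noise_cap_pf,
                                      seed = profile$seed + 1L)
  noise_px <- profile$noise_nh_mm / layout$mm_per_px
  markers <- render_marker_frames(nh, layout, frame_rate_hz = 114,
                                  sync_origin = 0L, noise_px = noise_px,
                                  seed = profile$seed + 2L,
                                  strain_rate_hz = sensor$sample_rate_hz)
  structure(list(truth = nh$truth, strain_series = strain,
                 marker_series = markers, elongation_true_mm = elong,
                 nh = nh, profile = profile, sensor = sensor,
                 layout = layout),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf(paste0("<simulated_trial> %d steps, true mean ND %.2f mm, ",
                     "%d strain samples, %d frames\n"),
              nrow(x$truth), mean(x$truth$nd_true_mm),
              nrow(x$strain_series),
              length(unique(x$marker_series$frame))))
  invisible(x)
}
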