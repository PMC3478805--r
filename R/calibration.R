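#' Fit the linear capacitance-to-elongation calibration
#'
#' Ordinary least squares of extension on capacitance over a calibration
#' sweep (the sensor strained in steps of at most 0.5 mm up to 20 mm, its
#' capacitance read at each extension). The regression orientation gives
#' the slope directly in mm/pF. R-squared is computed on the fit and is
#' exactly 1 on collinear input.
#'
#' @param sweep data frame with columns \code{capacitance_pF} and
#'   \code{extension_mm}; at least 2 distinct capacitances.
#' @param label free-text label stored in the model (e.g. the date).
#' @return a \code{\link{calibration_model}}.
#' @export
fit_calibration <- function(sweep, label = "") {
  if (!all(c("capacitance_pF", "extension_mm") %in% names(sweep)))
    stop("sweep needs columns capacitance_pF and extension_mm")
  x <- sweep$capacitance_pF
  y <- sweep$extension_mm
  if (length(unique(x)) < 2L)
    stop("degenerate sweep: all capacitances equal")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) {
    if (rss < 1e-20) 1 else 0
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  calibration_model(slope_mm_per_pf = slope, intercept_mm = intercept,
                    r_squared = r2, n_points = length(x), label = label)
}

#' Two-point everyday calibration
#'
#' Line through two (capacitance, extension) measurements -- the everyday
#' field calibration the linear transduction permits. Carries no R-squared:
#' a two-point fit is exact by construction, and reporting 1.0 would be a
#' meaningless quality claim.
#'
#' @param p_low,p_high length-2 vectors \code{c(capacitance_pF,
#'   extension_mm)}; distinct capacitances. Argument order does not matter.
#' @param label free-text label.
#' @return a \code{\link{calibration_model}} with \code{r_squared = NA}.
#' @export
two_point_calibrate <- function(p_low, p_high, label = "") {
  stopifnot(length(p_low) == 2L, length(p_high) == 2L)
  if (p_low[1] == p_high[1])
    stop("degenerate calibration: identical capacitances")
  slope <- (p_high[2] - p_low[2]) / (p_high[1] - p_low[1])
  intercept <- p_low[2] - slope * p_low[1]
  calibration_model(slope_mm_per_pf = unname(slope),
                    intercept_mm = unname(intercept),
                    r_squared = NA_real_, n_points = 2L, label = label)
}

#' Apply a calibration model to a capacitance record
#'
#' Elementwise affine map \code{elongation = slope * C + intercept};
#' length and timestamps untouched.
#'
#' @param series a \code{\link{strain_series}} with a \code{capacitance_pF}
#'   column.
#' @param model a \code{\link{calibration_model}}.
#' @return the series with an \code{elongation_mm} column added/replaced.
#' @export
apply_calibration <- function(series, model) {
  stopifnot(inherits(series, "strain_series"),
            inherits(model, "calibration_model"))
  if (is.null(series$capacitance_pF))
    stop("series has no capacitance_pF column")
  series$elongation_mm <- model$slope_mm_per_pf * series$capacitance_pF +
    model$intercept_mm
  series
}

#' Relative slope change between two calibrations
#'
#' Absolute percent change of the transduction slope from one calibration
#' session to another, \code{100 * |slope_b - slope_a| / |slope_a|} -- the
#' drift statistic tracked across repeated calibrations.
#'
#' @param model_a reference \code{\link{calibration_model}}.
#' @param model_b later \code{\link{calibration_model}}.
#' @return percent slope change (non-negative).
#' @export
slope_drift <- function(model_a, model_b) {
  if (model_a$slope_mm_per_pf == 0)
    stop("zero reference slope")
  100 * abs(model_b$slope_mm_per_pf - model_a$slope_mm_per_pf) /
    abs(model_a$slope_mm_per_pf)
}

#' Worst-case drop error implied by a slope drift
#'
#' A relative slope error of \code{drift_pct} percent scales every measured
#' elongation by the same factor, so the worst-case absolute error on a
#' navicular drop of \code{nd_mm} is \code{nd_mm * drift_pct / 100}
#' (e.g. 4% drift on a 10 mm drop gives 0.4 mm).
#'
#' @param drift_pct slope drift in percent, >= 0.
#' @param nd_mm navicular drop, mm, >= 0.
#' @return worst-case absolute drop error, mm.
#' @export
drift_to_accuracy <- function(drift_pct, nd_mm) {
  if (drift_pct < 0 || nd_mm < 0) stop("inputs must be >= 0")
  nd_mm * drift_pct / 100
}

#' Simulate a calibration sweep with the sensor transduction model
#'
#' Renders the bench calibration procedure in the simulator: the sensor is
#' extended in fixed steps and its quantized capacitance recorded at each
#' extension, giving a sweep table \code{\link{fit_calibration}} can fit.
#'
#' @param sensor a \code{\link{sensor_model}}.
#' @param extensions_mm extension grid, mm (default 0 to 20 by 0.5, i.e.
#'   up to 50% strain of the default 40 mm rest length).
#' @param noise_sd_pf SD of capacitance measurement noise, pF.
#' @param seed RNG seed for the noise.
#' @return data frame \code{capacitance_pF, extension_mm}.
#' @export
simulate_calibration_sweep <- function(sensor = sensor_model(),
                                       extensions_mm = seq(0, 20, by = 0.5),
                                       noise_sd_pf = 0, seed = NULL) {
  stopifnot(inherits(sensor, "sensor_model"))
  limit <- sensor$max_strain_frac * sensor$rest_length_mm
  if (any(extensions_mm > limit))
    stop("over-strain: sweep exceeds the maximal tolerated strain")
  cap <- sensor$intercept_pf + extensions_mm / sensor$slope_mm_per_pf
  if (noise_sd_pf > 0) {
    if (!is.null(seed)) set.seed(seed)
    cap <- cap + stats::rnorm(length(cap), 0, noise_sd_pf)
  }
  cap <- round(cap / sensor$quant_pf) * sensor$quant_pf
  data.frame(capacitance_pF = cap, extension_mm = extensions_mm)
}
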