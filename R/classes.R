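#' Uniformly sampled strain-sensor record
#'
#' A \code{strain_series} is a data frame with a time column \code{t_s}
#' (seconds, strictly increasing, nominally uniform) and one or both of
#' \code{capacitance_pF} (raw sensor output) and \code{elongation_mm}
#' (calibrated sensor elongation). The nominal sampling rate is carried as
#' the \code{rate_hz} attribute (200 Hz for the sensor hardware modeled
#' here).
#'
#' @param t_s numeric vector of sample times in seconds, strictly increasing.
#' @param capacitance_pF optional numeric vector of capacitances in pF.
#' @param elongation_mm optional numeric vector of elongations in mm.
#' @param rate_hz nominal sampling rate in Hz.
#' @return an object of class \code{strain_series}.
#' @export
strain_series <- function(t_s, capacitance_pF = NULL, elongation_mm = NULL,
                          rate_hz = 200) {
  if (is.null(capacitance_pF) && is.null(elongation_mm))
    stop("strain_series needs capacitance_pF and/or elongation_mm")
  n <- length(t_s)
  if (n < 1L || anyNA(t_s) || any(diff(t_s) <= 0))
    stop("t_s must be non-empty and strictly increasing")
  df <- data.frame(t_s = as.numeric(t_s))
  if (!is.null(capacitance_pF)) {
    stopifnot(length(capacitance_pF) == n)
    df$capacitance_pF <- as.numeric(capacitance_pF)
  }
  if (!is.null(elongation_mm)) {
    stopifnot(length(elongation_mm) == n)
    df$elongation_mm <- as.numeric(elongation_mm)
  }
  structure(df, rate_hz = rate_hz,
            class = c("strain_series", "data.frame"))
}

#' @export
print.strain_series <- function(x, ...) {
  cat(sprintf("<strain_series> %d samples @ %g Hz, %.2f s, columns: %s\n",
              nrow(x), attr(x, "rate_hz"),
              x$t_s[nrow(x)] - x$t_s[1],
              paste(setdiff(names(x), "t_s"), collapse = ", ")))
  invisible(x)
}

#' Marker-frame stream from the video reference system
#'
#' Long-format per-frame marker observations at the camera frame rate
#' (114 Hz): one row per (frame, marker). Each frame additionally carries a
#' 16-bit sync word (the strain-sample number displayed in gray code on the
#' sync box, decoded from LED states to an integer word here) and a logical
#' fiducial flag (the two always-on LEDs): frames whose fiducials are not
#' both lit cannot be trusted and are excluded from synchronization.
#'
#' @param frame integer frame numbers (non-decreasing; equal within a frame's
#'   marker rows).
#' @param t_s frame times in seconds.
#' @param marker_id character marker labels (e.g. "A", "B", "NAV").
#' @param x_px,y_px pixel coordinates (image convention: y grows downward).
#' @param sync_word integer gray-code words in [0, 65535], identical within
#'   a frame.
#' @param fiducial_ok logical, both fiducial LEDs detected.
#' @param rate_hz nominal frame rate in Hz.
#' @return an object of class \code{marker_frames}.
#' @export
marker_frames <- function(frame, t_s, marker_id, x_px, y_px,
                          sync_word, fiducial_ok, rate_hz = 114) {
  n <- length(frame)
  stopifnot(length(t_s) == n, length(marker_id) == n, length(x_px) == n,
            length(y_px) == n, length(sync_word) == n,
            length(fiducial_ok) == n)
  if (anyNA(sync_word) || any(sync_word < 0 | sync_word > 65535))
    stop("sync_word must be a 16-bit integer (0..65535)")
  df <- data.frame(frame = as.integer(frame), t_s = as.numeric(t_s),
                   marker_id = as.character(marker_id),
                   x_px = as.numeric(x_px), y_px = as.numeric(y_px),
                   sync_word = as.integer(sync_word),
                   fiducial_ok = as.logical(fiducial_ok))
  if (anyDuplicated(df[, c("frame", "marker_id")]))
    stop("duplicate (frame, marker_id) rows")
  structure(df, rate_hz = rate_hz,
            class = c("marker_frames", "data.frame"))
}

#' @export
print.marker_frames <- function(x, ...) {
  cat(sprintf("<marker_frames> %d frames x %d markers @ %g Hz\n",
              length(unique(x$frame)), length(unique(x$marker_id)),
              attr(x, "rate_hz")))
  invisible(x)
}

#' Linear capacitance-to-elongation calibration model
#'
#' Sensor elongation (mm) as an affine function of measured capacitance
#' (pF): \code{elongation = slope_mm_per_pf * C + intercept_mm}. Fitted
#' either by ordinary least squares on a calibration sweep
#' (\code{\link{fit_calibration}}) or through two points in everyday use
#' (\code{\link{two_point_calibrate}}, which carries no R-squared).
#'
#' @param slope_mm_per_pf slope in mm per pF, finite and nonzero.
#' @param intercept_mm elongation at zero capacitance, mm.
#' @param r_squared coefficient of determination of the fit, or NA for
#'   two-point calibrations.
#' @param n_points number of sweep points used (>= 2).
#' @param label free-text label (e.g. calibration date).
#' @return an object of class \code{calibration_model}.
#' @export
calibration_model <- function(slope_mm_per_pf, intercept_mm,
                              r_squared = NA_real_, n_points = 2L,
                              label = "") {
  if (!is.finite(slope_mm_per_pf) || slope_mm_per_pf == 0)
    stop("slope must be finite and nonzero")
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12))
    stop("r_squared must lie in [0, 1]")
  if (n_points < 2L) stop("n_points must be >= 2")
  structure(list(slope_mm_per_pf = slope_mm_per_pf,
                 intercept_mm = intercept_mm,
                 r_squared = r_squared,
                 n_points = as.integer(n_points),
                 label = label),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> slope %.6g mm/pF, intercept %.6g mm",
              x$slope_mm_per_pf, x$intercept_mm))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 %.6f", x$r_squared))
  cat(sprintf(" (n = %d%s)\n", x$n_points,
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Per-step gait events on one stream
#'
#' One row per detected step with sample indices (1-based, on the owning
#' stream's timeline) of heel strike (HS), lowest navicular height (NHL) and
#' toe off (TO), plus the step window bounds. The ordering invariant
#' \code{start <= hs < nhl < to <= end} is enforced.
#'
#' @param step integer step numbers.
#' @param hs_index,nhl_index,to_index event sample indices.
#' @param start,end step window bounds (sample indices).
#' @param stream_id which stream the indices refer to (e.g. "mvsa", "pbs").
#' @param mode detection mode: "mvsa", "pbs" (reference-anchored) or
#'   "standalone" (in-shoe, no video reference).
#' @return an object of class \code{step_events}.
#' @export
step_events <- function(step, hs_index, nhl_index, to_index, start, end,
                        stream_id = "mvsa", mode = "mvsa") {
  df <- data.frame(step = as.integer(step), hs_index = as.integer(hs_index),
                   nhl_index = as.integer(nhl_index),
                   to_index = as.integer(to_index),
                   start = as.integer(start), end = as.integer(end))
  ok <- with(df, start <= hs_index & hs_index < nhl_index &
               nhl_index < to_index & to_index <= end)
  if (nrow(df) > 0 && !all(ok))
    stop("event ordering violated: need start <= hs < nhl < to <= end")
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)] - 1L))
    stop("step windows must be ordered and non-overlapping")
  structure(df, stream_id = stream_id, mode = mode,
            class = c("step_events", "data.frame"))
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d steps on stream '%s' (mode %s)\n",
              nrow(x), attr(x, "stream_id"), attr(x, "mode")))
  invisible(x)
}

#' Marker displacement point cloud in the local foot frame
#'
#' @param points two-column numeric matrix (x, y) of local-frame
#'   displacements, mm or px.
#' @param marker_id label of the marker the cloud belongs to.
#' @return an object of class \code{point_cloud}.
#' @export
point_cloud <- function(points, marker_id = "") {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L || !all(is.finite(points)))
    stop("points must be a finite n x 2 matrix with n >= 1")
  colnames(points) <- c("x", "y")
  structure(list(points = points, marker_id = marker_id),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> '%s', %d points\n", x$marker_id,
              nrow(x$points)))
  invisible(x)
}
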