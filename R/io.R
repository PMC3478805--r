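# File formats: plain CSV with fixed, unit-suffixed headers for the two
# sample streams, JSON for models, truth records, sync maps and reports.
# Times are seconds, lengths mm, capacitances pF throughout.

# 17 significant digits: doubles survive the write/read round trip exactly
fmt_full <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  df
}

#' Write / read a strain-sensor CSV
#'
#' Columns \code{t_s} plus \code{capacitance_pF} and/or
#' \code{elongation_mm}. The reader validates the header, requires strictly
#' increasing time, and checks the inferred sampling rate against the
#' expected rate (200 Hz by default, 1% tolerance).
#'
#' @param series a \code{\link{strain_series}}.
#' @param path file path.
#' @param expected_rate_hz expected sampling rate, or NULL to skip the
#'   check.
#' @param rate_tol relative rate tolerance.
#' @return \code{read_strain_csv} returns a \code{\link{strain_series}};
#'   \code{write_strain_csv} returns \code{path} invisibly.
#' @rdname strain_csv
#' @export
write_strain_csv <- function(series, path) {
  stopifnot(inherits(series, "strain_series"))
  utils::write.csv(fmt_full(as.data.frame(series)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname strain_csv
#' @export
read_strain_csv <- function(path, expected_rate_hz = 200, rate_tol = 0.01) {
  df <- utils::read.csv(path, check.names = TRUE)
  if (!"t_s" %in% names(df))
    stop(sprintf("%s: missing column t_s", path))
  has_cap <- "capacitance_pF" %in% names(df)
  has_el <- "elongation_mm" %in% names(df)
  if (!has_cap && !has_el)
    stop(sprintf("%s: need capacitance_pF or elongation_mm", path))
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad) > 0)
    stop(sprintf("%s: non-monotone time at line %d", path, bad[1] + 2L))
  rate <- 1 / stats::median(diff(df$t_s))
  if (!is.null(expected_rate_hz) &&
      abs(rate - expected_rate_hz) > rate_tol * expected_rate_hz)
    stop(sprintf("%s: inferred rate %.2f Hz outside %g Hz +/- %g%%",
                 path, rate, expected_rate_hz, 100 * rate_tol))
  strain_series(df$t_s,
                capacitance_pF = if (has_cap) df$capacitance_pF,
                elongation_mm = if (has_el) df$elongation_mm,
                rate_hz = rate)
}

#' Write / read a marker-frame CSV
#'
#' Long format, one row per (frame, marker):
#' \code{frame, t_s, marker_id, x_px, y_px, sync_word_hex, fiducial_ok}.
#' Sync words are stored as 4-digit hex. The reader validates the header,
#' rejects duplicate (frame, marker) rows and checks the frame rate
#' (114 Hz by default, 1% tolerance).
#'
#' @param frames a \code{\link{marker_frames}} object.
#' @param path file path.
#' @param expected_rate_hz expected frame rate, or NULL to skip the check.
#' @param rate_tol relative rate tolerance.
#' @return \code{read_marker_csv} returns a \code{\link{marker_frames}};
#'   \code{write_marker_csv} returns \code{path} invisibly.
#' @rdname marker_csv
#' @export
write_marker_csv <- function(frames, path) {
  stopifnot(inherits(frames, "marker_frames"))
  df <- as.data.frame(frames)
  df$sync_word_hex <- sprintf("%04x", df$sync_word)
  df$sync_word <- NULL
  df <- df[, c("frame", "t_s", "marker_id", "x_px", "y_px",
               "sync_word_hex", "fiducial_ok")]
  utils::write.csv(fmt_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname marker_csv
#' @export
read_marker_csv <- function(path, expected_rate_hz = 114, rate_tol = 0.01) {
  need <- c("frame", "t_s", "marker_id", "x_px", "y_px", "sync_word_hex",
            "fiducial_ok")
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  miss <- setdiff(need, gsub("\"", "", hdr))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  df <- utils::read.csv(path, check.names = TRUE,
                        colClasses = c(sync_word_hex = "character"))
  ft <- df$t_s[!duplicated(df$frame)]
  if (length(ft) > 1) {
    rate <- 1 / stats::median(diff(sort(ft)))
    if (!is.null(expected_rate_hz) &&
        abs(rate - expected_rate_hz) > rate_tol * expected_rate_hz)
      stop(sprintf("%s: inferred frame rate %.2f Hz outside %g Hz +/- %g%%",
                   path, rate, expected_rate_hz, 100 * rate_tol))
  } else {
    rate <- expected_rate_hz
  }
  marker_frames(df$frame, df$t_s, df$marker_id, df$x_px, df$y_px,
                strtoi(df$sync_word_hex, base = 16L),
                as.logical(df$fiducial_ok), rate_hz = rate)
}

#' Write / read a calibration model as JSON
#'
#' @param model a \code{\link{calibration_model}}.
#' @param path file path.
#' @return \code{read_calibration_json} returns the model;
#'   \code{write_calibration_json} returns \code{path} invisibly.
#' @rdname calibration_json
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$slope_mm_per_pf, x$intercept_mm,
                    r_squared = if (is.null(x$r_squared)) NA_real_
                                else x$r_squared,
                    n_points = x$n_points,
                    label = if (is.null(x$label)) "" else x$label)
}

#' Write / read a per-step truth record as JSON
#'
#' One record per step: \code{step, t_hs_s, t_nhl_s, t_to_s, nd_true_mm}.
#'
#' @param truth truth data frame (as in a \code{simulated_trial}).
#' @param path file path.
#' @return \code{read_truth_json} returns the data frame;
#'   \code{write_truth_json} returns \code{path} invisibly.
#' @rdname truth_json
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a sync map as JSON records
#'
#' @param syncmap a \code{sync_map} from \code{\link{decode_frames}}.
#' @param path file path.
#' @export
write_sync_json <- function(syncmap, path) {
  stopifnot(inherits(syncmap, "sync_map"))
  jsonlite::write_json(
    list(frames = as.data.frame(syncmap),
         offset_stats = as.list(attr(syncmap, "offset_stats"))),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write step events as CSV
#'
#' Columns \code{step, stream_id, hs_index, nhl_index, to_index, start,
#' end, mode}.
#'
#' @param events a \code{\link{step_events}} object.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "step_events"))
  df <- as.data.frame(events)
  df$stream_id <- attr(events, "stream_id")
  df$mode <- attr(events, "mode")
  df <- df[, c("step", "stream_id", "hs_index", "nhl_index", "to_index",
               "start", "end", "mode")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trial report as JSON (plus a per-step CSV next to it)
#'
#' @param report a \code{\link{trial_report}}.
#' @param path JSON file path; the per-step table goes to the same path
#'   with extension \code{_steps.csv}.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "trial_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  csv <- sub("\\.json$", "", path)
  utils::write.csv(report$per_step, paste0(csv, "_steps.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# md5 of the canonical JSON rendering of a config list; recorded in outputs
# for provenance.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tf))
}
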