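#' Run the full two-stream analysis on synchronized recordings
#'
#' The bare-foot validation chain: decode the gray-code sync words, build
#' the navicular-height signal from the marker stream, upsample it onto the
#' 200 Hz strain timeline, detect video-side events, calibrate the
#' capacitance record to elongation, detect sensor-side events anchored to
#' the video events, and compute the per-step drop from both streams.
#'
#' @param strain a \code{\link{strain_series}} with capacitances.
#' @param markers a \code{\link{marker_frames}} object.
#' @param model a \code{\link{calibration_model}}.
#' @param mm_per_px metric scale of the camera image.
#' @param smooth_samples event-localization smoother width.
#' @return list with \code{nd_mvsa_mm}, \code{nd_pbs_mm} (paired per-step
#'   drops), \code{mvsa_events}, \code{pbs_events}, \code{syncmap},
#'   \code{nh_mm} (NH on the strain timeline) and \code{elongation_mm}.
#' @export
analyze_trial <- function(strain, markers, model, mm_per_px = 0.2,
                          smooth_samples = 5L) {
  stopifnot(inherits(strain, "strain_series"),
            inherits(markers, "marker_frames"))
  n <- nrow(strain)
  sm <- decode_frames(markers, n_samples = n)
  hs <- marker_height_series(markers, mm_per_px = mm_per_px)
  vals <- hs$nh_mm[match(sm$frame, hs$frame)]
  nh200 <- upsample_to_strain_timeline(vals, sm, n)
  ok <- which(!is.na(nh200))
  if (length(ok) < 10L) stop("frame span barely overlaps the strain series")
  i0 <- ok[1]
  i1 <- ok[length(ok)]
  rate <- attr(strain, "rate_hz")
  ev <- detect_mvsa_events(nh200[i0:i1], rate, smooth_samples = smooth_samples)
  mvsa_events <- step_events(ev$step, ev$hs_index + i0 - 1L,
                             ev$nhl_index + i0 - 1L, ev$to_index + i0 - 1L,
                             ev$start + i0 - 1L, ev$end + i0 - 1L,
                             stream_id = "mvsa", mode = "mvsa")
  cal <- apply_calibration(strain, model)
  elong <- cal$elongation_mm
  pbs_events <- detect_pbs_events(elong, mvsa_events,
                                  smooth_samples = smooth_samples)
  paired <- match(pbs_events$start, mvsa_events$start)
  list(nd_mvsa_mm = nd_from_mvsa(nh200, mvsa_events)[paired],
       nd_pbs_mm = nd_from_pbs(elong, pbs_events),
       mvsa_events = mvsa_events, pbs_events = pbs_events,
       syncmap = sm, nh_mm = nh200, elongation_mm = elong)
}

#' Run a configured workflow end to end
#'
#' Executes one of the three modes and writes its artifacts under
#' \code{config$out_dir}:
#' \describe{
#'   \item{simulate}{generate a synthetic trial; writes \code{strain.csv},
#'     \code{markers.csv}, \code{truth.json}, \code{calibration.json}.}
#'   \item{validate}{two-stream bare-foot analysis; writes
#'     \code{report.json} (+ per-step CSV), \code{sync.json}, event CSVs.
#'     With retest paths present, adds the retest block with test-retest
#'     change p-values.}
#'   \item{inshoe}{standalone sensor-only analysis; writes
#'     \code{inshoe_report.json}; with a barefoot strain path present also
#'     reports the in-shoe/barefoot mean-drop ratio.}
#' }
#' Every JSON artifact embeds the seed and a hash of the configuration.
#' Deterministic given \code{config$seed}.
#'
#' @param config a list: \code{mode} ("simulate", "validate" or "inshoe"),
#'   \code{seed}, \code{out_dir}, optional \code{profile}, \code{sensor},
#'   \code{layout} parameter blocks (passed to \code{\link{gait_profile}},
#'   \code{\link{sensor_model}}, \code{\link{marker_layout}}), and mode
#'   paths: \code{strain_csv}, \code{marker_csv}, \code{calibration_json},
#'   \code{sweep_csv}, \code{retest_strain_csv}, \code{retest_marker_csv},
#'   \code{barefoot_strain_csv}.
#' @return the mode's main result (a \code{simulated_trial}, a
#'   \code{\link{trial_report}}, or the in-shoe summary list), invisibly.
#' @export
run_workflow <- function(config) {
  mode <- config$mode
  if (is.null(mode) || !mode %in% c("simulate", "validate", "inshoe"))
    stop("config$mode must be simulate, validate or inshoe")
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  chash <- config_hash(config)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[navdrop] %-10s %6.1f s",
                                          name, proc.time()[["elapsed"]] - t0))
  layout <- do.call(marker_layout, as.list(config$layout))
  out <- switch(mode,
    simulate = {
      prof_args <- as.list(config$profile)
      prof_args$seed <- seed
      profile <- do.call(gait_profile, prof_args)
      sensor <- do.call(sensor_model, as.list(config$sensor))
      trial <- generate_trial(profile, sensor, layout)
      stage("simulate")
      write_strain_csv(trial$strain_series, file.path(out_dir, "strain.csv"))
      write_marker_csv(trial$marker_series, file.path(out_dir, "markers.csv"))
      write_truth_json(c(list(seed = seed, config_hash = chash),
                         list(steps = trial$truth)),
                       file.path(out_dir, "truth.json"))
      sweep <- simulate_calibration_sweep(sensor)
      write_calibration_json(fit_calibration(sweep, label = "simulated"),
                             file.path(out_dir, "calibration.json"))
      stage("write")
      trial
    },
    validate = {
      strain <- read_strain_csv(config$strain_csv)
      markers <- read_marker_csv(config$marker_csv)
      model <- load_calibration(config)
      stage("read")
      res <- analyze_trial(strain, markers, model,
                           mm_per_px = layout$mm_per_px)
      message(sprintf("[navdrop] %d paired steps", length(res$nd_mvsa_mm)))
      stage("analyze")
      retest <- NULL
      if (!is.null(config$retest_strain_csv)) {
        strain2 <- read_strain_csv(config$retest_strain_csv)
        markers2 <- read_marker_csv(config$retest_marker_csv)
        res2 <- analyze_trial(strain2, markers2, model,
                              mm_per_px = layout$mm_per_px)
        retest <- list(nd_mvsa = res2$nd_mvsa_mm, nd_pbs = res2$nd_pbs_mm)
        stage("retest")
      }
      report <- trial_report(res$nd_mvsa_mm, res$nd_pbs_mm, retest = retest,
                            seed = seed, config_hash = chash)
      write_report_json(report, file.path(out_dir, "report.json"))
      write_sync_json(res$syncmap, file.path(out_dir, "sync.json"))
      write_events_csv(res$mvsa_events, file.path(out_dir, "events_mvsa.csv"))
      write_events_csv(res$pbs_events, file.path(out_dir, "events_pbs.csv"))
      stage("write")
      report
    },
    inshoe = {
      strain <- read_strain_csv(config$strain_csv)
      model <- load_calibration(config)
      cal <- apply_calibration(strain, model)
      ev <- detect_inshoe_events(cal$elongation_mm, attr(strain, "rate_hz"))
      nds <- nd_from_pbs(cal$elongation_mm, ev)
      summ <- session_summary(nds)
      stage("inshoe")
      result <- list(mode = "standalone", inshoe = summ, seed = seed,
                     config_hash = chash)
      if (!is.null(config$barefoot_strain_csv)) {
        bf <- read_strain_csv(config$barefoot_strain_csv)
        bf_cal <- apply_calibration(bf, model)
        bf_ev <- detect_inshoe_events(bf_cal$elongation_mm,
                                      attr(bf, "rate_hz"))
        bf_nds <- nd_from_pbs(bf_cal$elongation_mm, bf_ev)
        result$barefoot <- session_summary(bf_nds)
        result$inshoe_barefoot_ratio <- summ$mean_mm /
          result$barefoot$mean_mm
        stage("barefoot")
      }
      write_events_csv(ev, file.path(out_dir, "events_inshoe.csv"))
      jsonlite::write_json(result, file.path(out_dir, "inshoe_report.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
      stage("write")
      result
    })
  invisible(out)
}

# Calibration for a workflow: explicit model JSON wins, else fit a sweep CSV.
load_calibration <- function(config) {
  if (!is.null(config$calibration_json))
    return(read_calibration_json(config$calibration_json))
  if (!is.null(config$sweep_csv)) {
    sweep <- utils::read.csv(config$sweep_csv)
    return(fit_calibration(sweep))
  }
  stop("config needs calibration_json or sweep_csv")
}

# --key value / --flag argument list -> named list (flags become TRUE)
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher behind the \code{exec/navdrop} script:
#' \preformatted{
#' navdrop simulate  --out DIR [--seed N] [--config run.json]
#' navdrop calibrate --sweep sweep.csv --out model.json [--two-point]
#' navdrop sync      --markers m.csv --strain s.csv --out sync.json
#' navdrop events    --strain s.csv --calibration cal.json --out ev.csv
#'                   [--markers m.csv | --standalone]
#' navdrop analyze   --strain s.csv --markers m.csv --calibration cal.json
#'                   --out DIR [--retest-strain s2.csv --retest-markers m2.csv]
#' navdrop report    --report report.json
#' }
#' A \code{--config run.json} file provides any field of the
#' \code{\link{run_workflow}} configuration; explicit flags override it.
#' Logs go to stderr, data only to files.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 ok, 1 usage error, 2 data error.
#' @export
navdrop_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: navdrop simulate|calibrate|sync|events|analyze|report ...")
    1L
  }
  if (length(args) < 1L) return(usage())
  cmd <- args[1]
  opts <- tryCatch(parse_cli_args(args[-1]),
                   error = function(e) NULL)
  if (is.null(opts)) return(usage())
  config <- list()
  if (!is.null(opts$config))
    config <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  status <- tryCatch({
    switch(cmd,
      simulate = {
        config$mode <- "simulate"
        if (!is.null(opts$out)) config$out_dir <- opts$out
        if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
        run_workflow(config)
      },
      calibrate = {
        if (is.null(opts$sweep) || is.null(opts$out)) return(usage())
        sweep <- utils::read.csv(opts$sweep)
        model <- if (isTRUE(opts$two_point)) {
          if (nrow(sweep) != 2L)
            stop("--two-point needs exactly 2 sweep rows")
          two_point_calibrate(unlist(sweep[1, c("capacitance_pF",
                                                "extension_mm")]),
                              unlist(sweep[2, c("capacitance_pF",
                                                "extension_mm")]))
        } else fit_calibration(sweep)
        write_calibration_json(model, opts$out)
      },
      sync = {
        if (is.null(opts$markers) || is.null(opts$strain) ||
            is.null(opts$out)) return(usage())
        strain <- read_strain_csv(opts$strain)
        markers <- read_marker_csv(opts$markers)
        write_sync_json(decode_frames(markers, n_samples = nrow(strain)),
                        opts$out)
      },
      events = {
        if (is.null(opts$strain) || is.null(opts$out)) return(usage())
        strain <- read_strain_csv(opts$strain)
        if (isTRUE(opts$standalone)) {
          config$calibration_json <- opts$calibration %||%
            config$calibration_json
          model <- load_calibration(config)
          cal <- apply_calibration(strain, model)
          ev <- detect_inshoe_events(cal$elongation_mm,
                                     attr(strain, "rate_hz"))
        } else {
          if (is.null(opts$markers)) return(usage())
          config$calibration_json <- opts$calibration %||%
            config$calibration_json
          model <- load_calibration(config)
          markers <- read_marker_csv(opts$markers)
          ev <- analyze_trial(strain, markers, model)$mvsa_events
        }
        write_events_csv(ev, opts$out)
      },
      analyze = {
        config$mode <- "validate"
        config$strain_csv <- opts$strain %||% config$strain_csv
        config$marker_csv <- opts$markers %||% config$marker_csv
        config$calibration_json <- opts$calibration %||%
          config$calibration_json
        config$retest_strain_csv <- opts$retest_strain %||%
          config$retest_strain_csv
        config$retest_marker_csv <- opts$retest_markers %||%
          config$retest_marker_csv
        if (!is.null(opts$out)) config$out_dir <- opts$out
        if (is.null(config$strain_csv) || is.null(config$marker_csv))
          return(usage())
        run_workflow(config)
      },
      report = {
        if (is.null(opts$report)) return(usage())
        x <- jsonlite::read_json(opts$report, simplifyVector = TRUE)
        message(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                                 digits = 4))
        invisible(NULL)
      },
      return(usage()))
    0L
  }, error = function(e) {
    message("[navdrop] error: ", conditionMessage(e))
    2L
  })
  status
}

`%||%` <- function(a, b) if (is.null(a)) b else a
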