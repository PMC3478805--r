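#' Per-step navicular drop from the video-derived height signal
#'
#' Drop of step k = NH(heel strike) - NH(lowest navicular height), read off
#' the raw series at the detected event indices.
#'
#' @param nh numeric navicular-height series, mm.
#' @param events a \code{\link{step_events}} object on the NH stream.
#' @return numeric vector of per-step drops, mm.
#' @export
nd_from_mvsa <- function(nh, events) {
  stopifnot(inherits(events, "step_events"))
  nh[events$hs_index] - nh[events$nhl_index]
}

#' Per-step navicular drop from the calibrated sensor signal
#'
#' Drop of step k = elongation(NHL) - elongation(HS): the calibrated sensor
#' elongation change in mm is taken as the drop estimate directly.
#'
#' @param elong numeric calibrated elongation series, mm.
#' @param events a \code{\link{step_events}} object on the sensor stream.
#' @return numeric vector of per-step drops, mm.
#' @export
nd_from_pbs <- function(elong, events) {
  stopifnot(inherits(events, "step_events"))
  elong[events$nhl_index] - elong[events$hs_index]
}

#' Session summary: mean navicular drop with a 95% confidence interval
#'
#' Arithmetic mean of the per-step drops with a t-based interval,
#' mean plus/minus t(0.975, n-1) * SD / sqrt(n).
#'
#' @param nds numeric per-step drops, mm; at least 2.
#' @param conf confidence level.
#' @return list \code{mean_mm, ci_low_mm, ci_high_mm, n}.
#' @export
session_summary <- function(nds, conf = 0.95) {
  n <- length(nds)
  if (n < 2L) stop("need at least 2 steps for a session summary")
  m <- mean(nds)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1L) * stats::sd(nds) / sqrt(n)
  list(mean_mm = m, ci_low_mm = m - half, ci_high_mm = m + half, n = n)
}

#' Paired comparison of video and sensor per-step drops
#'
#' Pearson product-moment correlation with a two-sided p-value from the
#' t-transform t = r sqrt((n-2)/(1-r^2)); mean per-step difference
#' (video minus sensor) with a t-based 95% CI; and the scatter table plus
#' the slope-one reference line offset (the line intersecting the y axis at
#' the mean difference) for agreement plots.
#'
#' @param nd_mvsa,nd_pbs equal-length per-step drop vectors, mm; n >= 3.
#' @param conf confidence level for the mean-difference interval.
#' @return list \code{pearson_r, p_value, n, mean_difference_mm,
#'   diff_ci_low_mm, diff_ci_high_mm, scatter} (data frame
#'   \code{nd_pbs_mm, nd_mvsa_mm}), \code{reference_intercept_mm}.
#' @export
paired_comparison <- function(nd_mvsa, nd_pbs, conf = 0.95) {
  n <- length(nd_mvsa)
  if (length(nd_pbs) != n) stop("paired vectors must have equal length")
  if (n < 3L) stop("need at least 3 paired steps")
  if (stats::sd(nd_mvsa) == 0 || stats::sd(nd_pbs) == 0)
    stop("correlation undefined: zero variance in one of the vectors")
  ct <- stats::cor.test(nd_mvsa, nd_pbs, method = "pearson",
                        conf.level = conf)
  d <- nd_mvsa - nd_pbs
  m <- mean(d)
  if (stats::sd(d) == 0) {
    lo <- hi <- m
  } else {
    tt <- stats::t.test(d, conf.level = conf)
    lo <- tt$conf.int[1]
    hi <- tt$conf.int[2]
  }
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n,
       mean_difference_mm = m, diff_ci_low_mm = lo, diff_ci_high_mm = hi,
       scatter = data.frame(nd_pbs_mm = nd_pbs, nd_mvsa_mm = nd_mvsa),
       reference_intercept_mm = m)
}

#' Two-sided p-value for a Pearson correlation via the t-transform
#'
#' Closed-form check of the correlation machinery:
#' t = r sqrt((n-2)/(1-r^2)) referred to a t distribution with n-2 degrees
#' of freedom, two-sided.
#'
#' @param r Pearson correlation coefficient, |r| < 1.
#' @param n number of pairs, n >= 3.
#' @return two-sided p-value.
#' @export
p_from_r <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 3L) stop("need n >= 3")
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Test-retest comparison of two sessions
#'
#' Difference of session means (retest minus test) with a two-sided Welch
#' two-sample t-test: the sessions have different step counts, so an
#' unpaired test is forced. Two identical degenerate sessions (zero
#' variance, equal means) return a difference of 0 with p = 1.
#'
#' @param session_a,session_b per-step drop vectors of the two sessions,
#'   each n >= 2.
#' @return list \code{mean_change_mm, p_value, n_a, n_b}.
#' @export
test_retest <- function(session_a, session_b) {
  if (length(session_a) < 2L || length(session_b) < 2L)
    stop("each session needs at least 2 steps")
  diff <- mean(session_b) - mean(session_a)
  if (stats::sd(session_a) == 0 && stats::sd(session_b) == 0) {
    p <- if (isTRUE(all.equal(diff, 0))) 1 else 0
  } else {
    p <- stats::t.test(session_a, session_b, var.equal = FALSE)$p.value
  }
  list(mean_change_mm = diff, p_value = p,
       n_a = length(session_a), n_b = length(session_b))
}

#' Assemble a trial report
#'
#' Bundles per-step drop pairs, per-stream session summaries, the paired
#' comparison and an optional retest block into the report object the
#' workflow writes to disk.
#'
#' @param nd_mvsa,nd_pbs paired per-step drops, mm.
#' @param retest optional list with elements \code{nd_mvsa, nd_pbs} of a
#'   second session.
#' @param seed RNG seed recorded for provenance.
#' @param config_hash configuration hash recorded for provenance.
#' @return an object of class \code{trial_report}.
#' @export
trial_report <- function(nd_mvsa, nd_pbs, retest = NULL, seed = NA_integer_,
                         config_hash = "") {
  cmp <- paired_comparison(nd_mvsa, nd_pbs)
  out <- list(
    per_step = data.frame(step = seq_along(nd_mvsa),
                          nd_mvsa_mm = nd_mvsa, nd_pbs_mm = nd_pbs),
    mvsa = session_summary(nd_mvsa),
    pbs = session_summary(nd_pbs),
    comparison = cmp[c("pearson_r", "p_value", "n", "mean_difference_mm",
                       "diff_ci_low_mm", "diff_ci_high_mm")],
    seed = seed, config_hash = config_hash)
  if (!is.null(retest)) {
    out$retest <- list(
      mvsa = session_summary(retest$nd_mvsa),
      pbs = session_summary(retest$nd_pbs),
      comparison = paired_comparison(retest$nd_mvsa, retest$nd_pbs)[
        c("pearson_r", "p_value", "n", "mean_difference_mm")],
      change_mvsa = test_retest(nd_mvsa, retest$nd_mvsa),
      change_pbs = test_retest(nd_pbs, retest$nd_pbs))
  }
  structure(out, class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %d paired steps\n", x$comparison$n))
  cat(sprintf("  video mean ND  %.2f mm (95%%CI %.2f; %.2f)\n",
              x$mvsa$mean_mm, x$mvsa$ci_low_mm, x$mvsa$ci_high_mm))
  cat(sprintf("  sensor mean ND %.2f mm (95%%CI %.2f; %.2f)\n",
              x$pbs$mean_mm, x$pbs$ci_low_mm, x$pbs$ci_high_mm))
  cat(sprintf("  mean difference %.2f mm (95%%CI %.2f; %.2f)\n",
              x$comparison$mean_difference_mm, x$comparison$diff_ci_low_mm,
              x$comparison$diff_ci_high_mm))
  cat(sprintf("  Pearson r %.3f (p = %.4g)\n", x$comparison$pearson_r,
              x$comparison$p_value))
  if (!is.null(x$retest))
    cat(sprintf("  retest: video change p = %.3g, sensor change p = %.3g\n",
                x$retest$change_mvsa$p_value, x$retest$change_pbs$p_value))
  invisible(x)
}

#' Match detected steps to a simulator truth record
#'
#' Pairs each detected step with the truth step whose lowest-navicular-
#' height time is nearest (within half a stride), for recovery checks of
#' the pipeline against the generator's ground truth.
#'
#' @param events a \code{\link{step_events}} object.
#' @param truth truth data frame of a \code{simulated_trial}.
#' @param t_s sample-time vector of the stream the events live on.
#' @return integer vector, one entry per event row: the matching truth row,
#'   or NA when no truth step lies within half a stride.
#' @export
match_events_to_truth <- function(events, truth, t_s) {
  stopifnot(inherits(events, "step_events"))
  stride <- stats::median(diff(truth$t_hs_s))
  det <- t_s[events$nhl_index]
  vapply(det, function(t) {
    j <- which.min(abs(truth$t_nhl_s - t))
    if (abs(truth$t_nhl_s[j] - t) <= stride / 2) j else NA_integer_
  }, integer(1))
}
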