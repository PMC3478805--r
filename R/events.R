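# Centered moving-average smoother used before event localization; values
# reported to the user are always read off the raw series at the detected
# indices, so smoothing affects localization only.
smooth_ma <- function(x, width = 5L) {
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  k <- rep(1 / width, width)
  out <- stats::filter(x, k, sides = 2)
  out <- as.numeric(out)
  h <- (width - 1L) %/% 2L
  out[seq_len(h)] <- out[h + 1L]
  n <- length(x)
  out[(n - h + 1L):n] <- out[n - h]
  out
}

#' Segment a periodic gait signal into steps
#'
#' Estimates the stride period from the autocorrelation of the signal,
#' anchors one dominant periodic feature per stride (the deepest trough for
#' a navicular-height signal, the highest peak for an elongation signal --
#' whichever deviates more from the median), and places step boundaries
#' midway between consecutive anchors.
#'
#' @param x numeric periodic 1-D signal.
#' @param rate_hz sampling rate, Hz.
#' @param min_period_s,max_period_s stride-period search range, seconds
#'   (defaults cover walking cadences).
#' @param min_acf minimal autocorrelation at the stride lag for the signal
#'   to count as periodic.
#' @param prominence_frac fraction of the maximal anchor deviation an
#'   anchor must reach, guards against spurious anchors in flat tails.
#' @return data frame \code{step, start, end, anchor} (sample indices),
#'   with attribute \code{period_samples}.
#' @export
segment_steps <- function(x, rate_hz, min_period_s = 0.4,
                          max_period_s = 2.0, min_acf = 0.3,
                          prominence_frac = 0.25) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0)
    stop("cannot segment: signal has no variation")
  maxlag <- min(n - 1L, ceiling(max_period_s * rate_hz))
  lo <- max(2L, floor(min_period_s * rate_hz))
  if (lo >= maxlag) stop("cannot segment: series too short for a stride")
  ac <- stats::acf(x - mean(x), lag.max = maxlag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lag_range <- lo:maxlag
  period <- lag_range[which.max(ac[lag_range + 1L])]
  if (ac[period + 1L] < min_acf)
    stop("cannot segment: no significant periodicity")
  med <- stats::median(x)
  use_max <- (max(x) - med) >= (med - min(x))
  s <- if (use_max) x - med else med - x
  dev_max <- max(s)
  thr <- prominence_frac * dev_max
  w1 <- min(n, ceiling(1.5 * period))
  a <- which.max(s[1:w1])
  anchors <- integer(0)
  if (s[a] >= thr) anchors <- a
  last <- a
  repeat {
    lo_w <- last + round(0.5 * period)
    hi_w <- min(n, last + round(1.5 * period))
    if (lo_w >= n || hi_w - lo_w < round(0.3 * period)) break
    cand <- lo_w - 1L + which.max(s[lo_w:hi_w])
    if (s[cand] >= thr) anchors <- c(anchors, cand)
    last <- if (s[cand] >= thr) cand else last + period
    if (last >= n) break
  }
  if (length(anchors) < 1L)
    stop("cannot segment: no periodic feature found")
  k <- length(anchors)
  edge <- round(0.6 * period)
  if (k == 1L) {
    starts <- max(1L, anchors - edge)
    ends <- min(n, anchors + edge)
  } else {
    mids <- floor((anchors[-k] + anchors[-1]) / 2)
    starts <- c(max(1L, anchors[1] - edge), mids)
    ends <- c(mids, min(n, anchors[k] + edge))
  }
  structure(data.frame(step = seq_len(k), start = as.integer(starts),
                       end = as.integer(ends), anchor = as.integer(anchors)),
            period_samples = period, class = "data.frame")
}

#' Detect heel strike, lowest navicular height and toe off per step
#'
#' Event rules on the (video-derived) navicular-height signal: within each
#' step window, NHL is the sample of minimum height; HS is the last sample
#' before the descent at which the height still attains its pre-descent
#' plateau level (localized as the final crossing of plateau minus
#' \code{h_frac} of the step's range before the minimum, refined back to
#' the plateau); TO is the first return to within the same threshold of the
#' plateau after the minimum. Steps with height range below 0.1 mm carry no
#' usable events and are skipped with a warning.
#'
#' @param nh numeric navicular-height series, mm (on the strain timeline
#'   after upsampling, or any uniformly sampled NH record).
#' @param rate_hz sampling rate, Hz.
#' @param steps optional step boundaries from \code{\link{segment_steps}};
#'   segmented internally when omitted.
#' @param h_frac descent/recovery crossing threshold as a fraction of the
#'   step's height range.
#' @param plateau_eps_frac tolerance for "attains the plateau", as a
#'   fraction of the step's height range.
#' @param smooth_samples moving-average width used for localization.
#' @return a \code{\link{step_events}} object on stream \code{"mvsa"}.
#' @export
detect_mvsa_events <- function(nh, rate_hz, steps = NULL, h_frac = 0.05,
                               plateau_eps_frac = 0.005,
                               smooth_samples = 5L) {
  if (is.null(steps)) steps <- segment_steps(nh, rate_hz)
  xs <- smooth_ma(nh, smooth_samples)
  rows <- vector("list", nrow(steps))
  for (i in seq_len(nrow(steps))) {
    s0 <- steps$start[i]
    s1 <- steps$end[i]
    seg <- xs[s0:s1]
    rng <- max(seg) - min(seg)
    if (rng < 0.1) {
      warning(sprintf("step %d skipped: flat (range %.3f mm)", i, rng))
      next
    }
    nhl_rel <- which.min(seg)
    if (nhl_rel <= 1L || nhl_rel >= length(seg)) next
    pre <- seg[1:(nhl_rel - 1L)]
    plat <- stats::quantile(pre, 0.9, names = FALSE)
    h <- h_frac * rng
    eps <- plateau_eps_frac * rng
    at_plateau <- which(pre >= plat - eps)
    if (length(at_plateau) == 0L) next
    hs_rel <- max(at_plateau)
    post <- seg[(nhl_rel + 1L):length(seg)]
    rec <- which(post >= plat - h)
    to_rel <- if (length(rec) > 0L) nhl_rel + rec[1] else length(seg)
    if (!(hs_rel < nhl_rel && nhl_rel < to_rel)) next
    rows[[i]] <- data.frame(step = i, hs = s0 - 1L + hs_rel,
                            nhl = s0 - 1L + nhl_rel, to = s0 - 1L + to_rel,
                            start = s0, end = s1)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no usable steps detected")
  step_events(seq_len(nrow(rows)), rows$hs, rows$nhl, rows$to,
              rows$start, rows$end, stream_id = "mvsa", mode = "mvsa")
}

#' Sensor-side heel strike near a reference heel strike
#'
#' The sensor's heel strike is the local elongation minimum inside a window
#' of plus/minus \code{window_frac} (10%) of the step length around the
#' video-derived heel-strike position; "step length" is read as step
#' duration in samples. Ties break to the earliest index. Windows reaching
#' past the series are clipped with a warning.
#'
#' @param elong numeric elongation series, mm.
#' @param mvsa_hs reference heel-strike sample index.
#' @param step_len step duration in samples.
#' @param window_frac half-window as a fraction of the step length.
#' @return sample index of the sensor-side heel strike.
#' @export
detect_pbs_hs <- function(elong, mvsa_hs, step_len, window_frac = 0.1) {
  w <- round(window_frac * step_len)
  lo <- mvsa_hs - w
  hi <- mvsa_hs + w
  n <- length(elong)
  if (lo < 1L || hi > n) {
    warning("heel-strike window clipped to the series bounds")
    lo <- max(1L, lo)
    hi <- min(n, hi)
  }
  lo - 1L + which.min(elong[lo:hi])
}

#' Sensor-side lowest navicular height within a step
#'
#' The lowest navicular height corresponds to maximal sensor strain: the
#' argmax of elongation within the step window, ties to the earliest index.
#'
#' @param elong numeric elongation series, mm.
#' @param start,end step window bounds (sample indices).
#' @return sample index of maximal elongation.
#' @export
detect_pbs_nhl <- function(elong, start, end) {
  if (end < start) stop("empty step window")
  start - 1L + which.max(elong[start:end])
}

#' Sensor-side events anchored to video-derived events
#'
#' Applies \code{\link{detect_pbs_hs}} and \code{\link{detect_pbs_nhl}} to
#' every step of a reference event set (both streams on the shared strain
#' timeline after synchronization). Toe off is carried over from the
#' reference events: the sensor rules define only HS and NHL.
#'
#' @param elong numeric elongation series, mm, on the strain timeline.
#' @param mvsa_events a \code{\link{step_events}} object from
#'   \code{\link{detect_mvsa_events}}.
#' @param smooth_samples moving-average width used for localization.
#' @param window_frac heel-strike half-window fraction.
#' @return a \code{\link{step_events}} object on stream \code{"pbs"}.
#' @export
detect_pbs_events <- function(elong, mvsa_events, smooth_samples = 5L,
                              window_frac = 0.1) {
  stopifnot(inherits(mvsa_events, "step_events"))
  xs <- smooth_ma(elong, smooth_samples)
  hs <- integer(nrow(mvsa_events))
  nhl <- integer(nrow(mvsa_events))
  keep <- logical(nrow(mvsa_events))
  for (i in seq_len(nrow(mvsa_events))) {
    len <- mvsa_events$end[i] - mvsa_events$start[i] + 1L
    hs[i] <- detect_pbs_hs(xs, mvsa_events$hs_index[i], len, window_frac)
    nhl[i] <- detect_pbs_nhl(xs, mvsa_events$start[i], mvsa_events$end[i])
    keep[i] <- hs[i] >= mvsa_events$start[i] && hs[i] < nhl[i] &&
      nhl[i] < mvsa_events$to_index[i]
  }
  if (!any(keep)) stop("no usable steps detected on the sensor stream")
  step_events(seq_len(sum(keep)), hs[keep], nhl[keep],
              mvsa_events$to_index[keep], mvsa_events$start[keep],
              mvsa_events$end[keep], stream_id = "pbs", mode = "pbs")
}

#' Standalone in-shoe event detection from the sensor alone
#'
#' In-shoe recordings have no video reference, so events come from the
#' elongation signal by itself: steps from \code{\link{segment_steps}};
#' per step, NHL is the elongation argmax and HS the bottom of the
#' characteristic pre-rise strain drop (the minimum preceding the step's
#' main rise). The result is flagged \code{mode = "standalone"}.
#'
#' @param elong numeric elongation series, mm.
#' @param rate_hz sampling rate, Hz.
#' @param smooth_samples moving-average width used for localization.
#' @return a \code{\link{step_events}} object, mode \code{"standalone"}.
#' @export
detect_inshoe_events <- function(elong, rate_hz, smooth_samples = 5L) {
  steps <- segment_steps(elong, rate_hz)
  xs <- smooth_ma(elong, smooth_samples)
  rows <- vector("list", nrow(steps))
  for (i in seq_len(nrow(steps))) {
    s0 <- steps$start[i]
    s1 <- steps$end[i]
    nhl <- detect_pbs_nhl(xs, s0, s1)
    if (nhl <= s0 || nhl >= s1) next
    hs <- s0 - 1L + which.min(xs[s0:(nhl - 1L)])
    if (!(hs < nhl)) next
    rows[[i]] <- data.frame(hs = hs, nhl = nhl, to = s1, start = s0,
                            end = s1)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no usable steps detected")
  step_events(seq_len(nrow(rows)), rows$hs, rows$nhl, rows$to,
              rows$start, rows$end, stream_id = "pbs", mode = "standalone")
}
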