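#' Binary-reflected gray code of an integer
#'
#' Encodes a sample number the way the sync box displays it on its 16 LEDs:
#' the binary-reflected gray code, in which successive integers differ in
#' exactly one bit. Bit vectors are LSB-first.
#'
#' @param n non-negative integer, \code{n < 2^width}.
#' @param width word width in bits (16 for the modeled sync box).
#' @return integer vector of \code{width} bits (0/1), least significant
#'   first.
#' @seealso \code{\link{gray_decode}}, \code{\link{gray_encode_int}}
#' @export
gray_encode <- function(n, width = 16L) {
  if (length(n) != 1L || is.na(n) || n < 0 || n >= 2^width)
    stop(sprintf("n must be a single integer in [0, 2^%d)", width))
  g <- gray_encode_int(as.integer(n))
  bitwAnd(bitwShiftR(g, 0:(width - 1L)), 1L)
}

#' Decode a gray-code bit vector to its integer
#'
#' Exact inverse of \code{\link{gray_encode}} (LSB-first bit order).
#'
#' @param bits integer vector of 0/1 bits, least significant first; at most
#'   16 bits (the sync box's LED count).
#' @return the decoded non-negative integer.
#' @export
gray_decode <- function(bits) {
  if (length(bits) > 16L) stop("at most 16 bits supported")
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
  g <- sum(bits * 2^(seq_along(bits) - 1L))
  gray_decode_int(as.integer(g))
}

#' Vectorized gray code on integer words
#'
#' \code{gray_encode_int} maps integers to their binary-reflected gray-code
#' words (\code{n XOR (n >> 1)}); \code{gray_decode_int} is the exact
#' inverse via prefix XOR. Both operate on whole vectors and are the
#' workhorses behind the per-frame sync words.
#'
#' @param n,g integer vectors of words in [0, 2^31).
#' @return integer vector of the same length.
#' @rdname gray_int
#' @export
gray_encode_int <- function(n) {
  n <- as.integer(n)
  if (anyNA(n) || any(n < 0)) stop("n must be non-negative integers")
  bitwXor(n, bitwShiftR(n, 1L))
}

#' @rdname gray_int
#' @export
gray_decode_int <- function(g) {
  g <- as.integer(g)
  if (anyNA(g) || any(g < 0)) stop("g must be non-negative integers")
  n <- g
  for (s in c(1L, 2L, 4L, 8L, 16L)) n <- bitwXor(n, bitwShiftR(n, s))
  n
}

#' Decode the per-frame sync words of a marker stream
#'
#' Builds the frame-to-sample synchronization map: frames whose fiducial
#' bits are off are invalid; valid gray words are decoded and unwrapped
#' modulo 2^16 by nearest continuation at the nominal rate ratio (200/114
#' strain samples per frame by default). Isolated decode glitches -- frames
#' whose unwrapped jump deviates from the expected increment by more than
#' \code{glitch_mult} per-frame increments -- are invalidated without
#' disturbing their neighbors.
#'
#' @param frames a \code{\link{marker_frames}} object.
#' @param strain_rate_hz,frame_rate_hz stream rates; their ratio sets the
#'   expected per-frame sample increment.
#' @param n_samples optional length of the strain series; decoded indices
#'   outside [0, n_samples) are invalidated.
#' @param glitch_mult glitch threshold in units of the expected per-frame
#'   increment.
#' @return a data frame of class \code{sync_map}: \code{frame, t_s,
#'   sample_index} (0-based, unwrapped; NA when invalid), \code{valid};
#'   attribute \code{offset_stats} summarizes residual timing offsets
#'   against a linear frame-time fit.
#' @export
decode_frames <- function(frames, strain_rate_hz = 200,
                          frame_rate_hz = NULL, n_samples = NULL,
                          glitch_mult = 3) {
  stopifnot(inherits(frames, "marker_frames"))
  if (is.null(frame_rate_hz)) frame_rate_hz <- attr(frames, "rate_hz")
  per <- frames[!duplicated(frames$frame),
                c("frame", "t_s", "sync_word", "fiducial_ok")]
  per <- per[order(per$frame), ]
  nf <- nrow(per)
  raw <- gray_decode_int(per$sync_word)
  ratio <- strain_rate_hz / frame_rate_hz
  idx <- rep(NA_real_, nf)
  valid <- logical(nf)
  last_i <- NA_integer_
  for (i in seq_len(nf)) {
    if (!per$fiducial_ok[i]) next
    if (is.na(last_i)) {
      idx[i] <- raw[i]
      valid[i] <- TRUE
      last_i <- i
      next
    }
    gap <- per$frame[i] - per$frame[last_i]
    jump <- (raw[i] - raw[last_i]) %% 65536
    expected <- gap * ratio
    if (abs(jump - expected) > glitch_mult * ratio) next
    idx[i] <- idx[last_i] + jump
    valid[i] <- TRUE
    last_i <- i
  }
  if (!is.null(n_samples)) {
    oob <- valid & (idx < 0 | idx >= n_samples)
    idx[oob] <- NA_real_
    valid[oob] <- FALSE
  }
  if (sum(valid) < 2L)
    stop("cannot sync: fewer than 2 valid frames")
  fit <- stats::lm.fit(cbind(1, per$t_s[valid]), idx[valid])
  res_ms <- fit$residuals / strain_rate_hz * 1000
  structure(data.frame(frame = per$frame, t_s = per$t_s,
                       sample_index = idx, valid = valid),
            offset_stats = c(mean_ms = mean(res_ms), sd_ms = stats::sd(res_ms),
                             max_abs_ms = max(abs(res_ms))),
            class = c("sync_map", "data.frame"))
}

#' Upsample a per-frame signal onto the strain-sample timeline
#'
#' Piecewise-linear interpolation of a 114 Hz frame-synchronous signal onto
#' the 200 Hz strain timeline, using the decoded sample indices of the sync
#' map as abscissae. Values at exactly frame-aligned samples reproduce the
#' frame values; samples outside the spanned range are not extrapolated and
#' come back NA.
#'
#' @param values numeric per-frame values, one per sync-map row.
#' @param syncmap a \code{sync_map} from \code{\link{decode_frames}}.
#' @param n_samples length of the target strain series.
#' @param method interpolation method, \code{"linear"} (default) or
#'   \code{"cubic"} (Hermite spline).
#' @param refine refine the integer decoded indices to fractional sample
#'   positions by a linear clock fit over the valid frames (default). The
#'   displayed sample numbers are whole samples, so raw decoded positions
#'   carry up to half a sample of rounding jitter; with steady clocks the
#'   fit removes it. Falls back to the raw indices when the fit residuals
#'   exceed half a sample (irregular timing).
#' @return numeric vector of length \code{n_samples}, NA outside the frame
#'   span.
#' @export
upsample_to_strain_timeline <- function(values, syncmap, n_samples,
                                        method = c("linear", "cubic"),
                                        refine = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(syncmap, "sync_map"), length(values) == nrow(syncmap))
  x <- syncmap$sample_index[syncmap$valid]
  y <- values[syncmap$valid]
  if (length(x) < 2L) stop("cannot upsample: fewer than 2 valid frames")
  if (refine) {
    tv <- syncmap$t_s[syncmap$valid]
    fit <- stats::lm.fit(cbind(1, tv), x)
    if (max(abs(fit$residuals)) <= 0.5 + 1e-9)
      x <- as.numeric(cbind(1, tv) %*% fit$coefficients)
  }
  xout <- seq_len(n_samples) - 1
  if (min(x) > max(xout) || max(x) < min(xout))
    stop("cannot upsample: frame span does not overlap the target timeline")
  if (method == "linear") {
    stats::approx(x, y, xout = xout, method = "linear", rule = 1,
                  ties = "ordered")$y
  } else {
    out <- rep(NA_real_, n_samples)
    inside <- xout >= min(x) & xout <= max(x)
    out[inside] <- stats::spline(x, y, xout = xout[inside],
                                 method = "fmm")$y
    out
  }
}

#' Transfer an event time from the camera timeline to the strain timeline
#'
#' Linearly interpolates the decoded sample index at an arbitrary camera
#' time and converts it to seconds on the strain clock.
#'
#' @param t_s event time(s) on the camera timeline, seconds.
#' @param syncmap a \code{sync_map}.
#' @param strain_rate_hz strain sampling rate.
#' @return event time(s) on the strain timeline, seconds.
#' @export
transfer_time <- function(t_s, syncmap, strain_rate_hz = 200) {
  stopifnot(inherits(syncmap, "sync_map"))
  ok <- syncmap$valid
  idx <- stats::approx(syncmap$t_s[ok], syncmap$sample_index[ok],
                       xout = t_s, rule = 1, ties = "ordered")$y
  idx / strain_rate_hz
}
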