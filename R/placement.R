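#' Transform one frame's markers into the local foot frame
#'
#' Rigid transform (translation + rotation, no scaling) defined by the two
#' reference markers: the calcaneus marker B maps to the local origin (0,0)
#' and the front-foot marker A to (|A - B|, 0) on the +x axis; every other
#' marker is transformed identically. Pixel coordinates keep the image
#' convention (y grows downward).
#'
#' @param markers data frame with columns \code{marker_id, x_px, y_px} for a
#'   single frame.
#' @param ref_a,ref_b marker ids of the front-foot (A) and calcaneus (B)
#'   reference markers.
#' @return the same data frame with \code{x_local, y_local} columns added.
#' @export
to_local_frame <- function(markers, ref_a = "A", ref_b = "B") {
  a <- markers[markers$marker_id == ref_a, c("x_px", "y_px")]
  b <- markers[markers$marker_id == ref_b, c("x_px", "y_px")]
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop("reference markers must appear exactly once in the frame")
  ax <- a$x_px - b$x_px
  ay <- a$y_px - b$y_px
  if (ax == 0 && ay == 0) stop("degenerate frame: A and B coincide")
  theta <- atan2(ay, ax)
  ct <- cos(theta)
  st <- sin(theta)
  dx <- markers$x_px - b$x_px
  dy <- markers$y_px - b$y_px
  markers$x_local <- ct * dx + st * dy
  markers$y_local <- -st * dx + ct * dy
  markers
}

#' Displacement point cloud of one marker over a trial
#'
#' Expresses a marker's per-frame local-frame coordinates as displacements
#' from the cloud centroid -- the scatter each marker traces out during
#' gait, used to pick the sensor attachment sites.
#'
#' @param series a \code{\link{marker_frames}} object.
#' @param marker marker id whose cloud is wanted.
#' @param ref_a,ref_b reference marker ids.
#' @param mm_per_px optional metric scale; when given the cloud is in mm.
#' @return a \code{\link{point_cloud}}.
#' @export
displacement_cloud <- function(series, marker, ref_a = "A", ref_b = "B",
                               mm_per_px = NULL) {
  stopifnot(inherits(series, "marker_frames"))
  frames <- sort(unique(series$frame))
  present <- unique(series$frame[series$marker_id == marker])
  if (length(present) < 2L)
    stop(sprintf("marker '%s' present in fewer than 2 frames", marker))
  missing_f <- setdiff(frames, present)
  if (length(missing_f) > 0)
    stop(sprintf("marker '%s' missing in frame %d", marker, missing_f[1]))
  loc <- local_coords(series, marker, ref_a, ref_b)
  pts <- cbind(loc$x, loc$y)
  if (!is.null(mm_per_px)) pts <- pts * mm_per_px
  pts <- sweep(pts, 2, colMeans(pts))
  point_cloud(pts, marker_id = marker)
}

# Vectorized local coordinates of one marker across all frames.
local_coords <- function(series, marker, ref_a = "A", ref_b = "B") {
  pick <- function(id) {
    m <- series[series$marker_id == id, c("frame", "x_px", "y_px")]
    m[order(m$frame), ]
  }
  a <- pick(ref_a)
  b <- pick(ref_b)
  m <- pick(marker)
  common <- Reduce(intersect, list(a$frame, b$frame, m$frame))
  a <- a[a$frame %in% common, ]
  b <- b[b$frame %in% common, ]
  m <- m[m$frame %in% common, ]
  ax <- a$x_px - b$x_px
  ay <- a$y_px - b$y_px
  if (any(ax == 0 & ay == 0)) stop("degenerate frame: A and B coincide")
  theta <- atan2(ay, ax)
  ct <- cos(theta)
  st <- sin(theta)
  dx <- m$x_px - b$x_px
  dy <- m$y_px - b$y_px
  list(frame = m$frame, t_s = NULL,
       x = ct * dx + st * dy, y = -st * dx + ct * dy)
}

#' Relative marker height series from the local frame
#'
#' Per-frame height of a marker above its mean position: the negated local
#' y coordinate (image y grows downward) scaled to mm. This is the
#' navicular-height signal, up to an arbitrary offset that cancels in the
#' heel-strike-to-minimum drop.
#'
#' @param series a \code{\link{marker_frames}} object.
#' @param marker marker id (the navicular marker).
#' @param ref_a,ref_b reference marker ids.
#' @param mm_per_px metric scale, mm per pixel.
#' @return data frame \code{frame, t_s, nh_mm} ordered by frame.
#' @export
marker_height_series <- function(series, marker = "NAV", ref_a = "A",
                                 ref_b = "B", mm_per_px = 0.2) {
  stopifnot(inherits(series, "marker_frames"))
  loc <- local_coords(series, marker, ref_a, ref_b)
  per <- series[!duplicated(series$frame), c("frame", "t_s")]
  per <- per[match(loc$frame, per$frame), ]
  nh <- -mm_per_px * loc$y
  data.frame(frame = loc$frame, t_s = per$t_s, nh_mm = nh - mean(nh))
}

#' Major axis of a displacement point cloud
#'
#' Principal eigenvector of the 2x2 coordinate covariance; the angle is
#' measured from the local +x axis and reported in [0, 180). Nearly
#' isotropic clouds (eigenvalue ratio below \code{min_ratio}) have no
#' meaningful major axis and raise an error rather than returning noise.
#'
#' @param cloud a \code{\link{point_cloud}} with at least 2 distinct points.
#' @param min_ratio minimal major/minor eigenvalue ratio for the axis to be
#'   considered defined.
#' @return list with \code{direction} (unit 2-vector) and \code{angle_deg}
#'   in [0, 180).
#' @export
major_axis <- function(cloud, min_ratio = 1.05) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points
  if (nrow(unique(pts)) < 2L) stop("need at least 2 distinct points")
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] > 0 && ev$values[1] / ev$values[2] < min_ratio)
    stop("axis undefined: point cloud is nearly isotropic")
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ang %% 180
  if (ang >= 180) ang <- ang - 180
  if (ang < 0) ang <- ang + 180
  list(direction = v / sqrt(sum(v^2)), angle_deg = ang)
}

#' Angle between the major axes of two point clouds
#'
#' Undirected angle between the two major-axis orientations, reported in
#' [0, 180) and symmetric in its arguments.
#'
#' @param cloud_a,cloud_b \code{\link{point_cloud}} objects.
#' @param min_ratio isotropy guard passed to \code{\link{major_axis}}.
#' @return angle in degrees, [0, 180).
#' @export
axis_angle_between <- function(cloud_a, cloud_b, min_ratio = 1.05) {
  aa <- major_axis(cloud_a, min_ratio)$angle_deg
  ab <- major_axis(cloud_b, min_ratio)$angle_deg
  d <- abs(aa - ab) %% 180
  d
}

#' Score a candidate sensor attachment pair
#'
#' The sensor measures strain along the line joining its two attachment
#' points, so motion of the upper attachment site along that line
#' contaminates the measurement. The score is the absolute cosine of the
#' angle between the upper cloud's major axis and the sensor line: 0 when
#' the upper site's dominant motion is perpendicular to the sensor (ideal,
#' least strain impact), 1 when parallel (worst). Lower is better.
#'
#' @param upper,lower \code{\link{point_cloud}}s of the candidate upper and
#'   lower attachment sites.
#' @param sensor_line direction of the sensor line: either an angle in
#'   degrees from local +x, or a length-2 direction vector.
#' @return list with \code{score}, \code{upper_angle_deg},
#'   \code{lower_angle_deg} and \code{between_deg} (angle between the two
#'   clouds' major axes).
#' @export
score_attachment_pair <- function(upper, lower, sensor_line) {
  if (length(sensor_line) == 2L)
    sensor_line <- atan2(sensor_line[2], sensor_line[1]) * 180 / pi
  au <- major_axis(upper)$angle_deg
  al <- major_axis(lower)$angle_deg
  delta <- abs(au - sensor_line %% 180)
  list(score = abs(cos(delta * pi / 180)),
       upper_angle_deg = au, lower_angle_deg = al,
       between_deg = abs(au - al) %% 180)
}

#' Rank candidate attachment pairs by strain-contamination score
#'
#' @param pairs list of lists, each with elements \code{upper}, \code{lower}
#'   (\code{\link{point_cloud}}s) and \code{sensor_line}.
#' @return data frame ordered by increasing score (best pair first), with
#'   the per-pair angles.
#' @export
rank_attachment_pairs <- function(pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    s <- score_attachment_pair(p$upper, p$lower, p$sensor_line)
    data.frame(pair = i, score = s$score,
               upper_angle_deg = s$upper_angle_deg,
               lower_angle_deg = s$lower_angle_deg,
               between_deg = s$between_deg)
  })
  out <- do.call(rbind, rows)
  out[order(out$score), ]
}
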