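#' Interior angle at a vertex
#'
#' Angle, in degrees, subtended at `b` by the segments `b->a` and `b->c`.
#' Inputs may be single points (length-2 vectors) or frames x 2 matrices;
#' the result is always in `[0, 180]`.
#'
#' @param a,b,c 2D points (length-2 numeric vectors or n x 2 matrices).
#' @return Numeric vector of angles in degrees.
#' @export
angle_at_vertex <- function(a, b, c) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, 1L, 2L)
  a <- as_m(a); b <- as_m(b); c <- as_m(c)
  u <- a - b
  v <- c - b
  nu <- row_norm(u[, 1], u[, 2])
  nv <- row_norm(v[, 1], v[, 2])
  if (any(nu == 0 | nv == 0))
    stop("undefined angle: vertex coincides with an endpoint")
  cosang <- (u[, 1] * v[, 1] + u[, 2] * v[, 2]) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# signed angle of vector v (n x 2) against the image vertical (0, 1),
# in degrees in [-180, 180)
signed_angle_to_vertical <- function(v) {
  ang <- atan2(v[, 1], v[, 2]) * 180 / pi   # cross((0,1), v) = vx; dot = vy
  ang[ang >= 180] <- ang[ang >= 180] - 360
  ang
}

#' Per-frame jump likelihood
#'
#' Tracking confidence is near-perfect while the animal is in frame and
#' collapses when it leaves it mid-jump, so the probability of a jump on a
#' frame is approximated as one minus the tracking confidence (the mean
#' likelihood over the 11 animal points; the static corners are excluded).
#'
#' @param track A [pose_track()].
#' @return Numeric vector, `P(jump)` per frame, in `[0, 1]`.
#' @export
jump_likelihood_series <- function(track) {
  1 - tracking_confidence(track)
}

# simple hysteresis-free sustained-condition detector used by the rearing proxy
sustained <- function(flag, min_frames) {
  r <- runs_of(flag)
  out <- rep(FALSE, length(flag))
  keep <- r[r$offset - r$onset + 1L >= min_frames, , drop = FALSE]
  if (nrow(keep))
    for (i in seq_len(nrow(keep))) out[keep$onset[i]:keep$offset[i]] <- TRUE
  out
}

#' Compute the per-frame kinematic variables
#'
#' Derives, from a corrected and calibrated pose track, the 14 relative
#' variables (body extension, shoulder distance, hip distance, mid-tail to
#' body-centre distance, tail extension, head extension, body-tail angle,
#' mid-tail angle, head-body angle, body rotation, distance to the box
#' centre, body torsion, speed and rearing) plus the jump-likelihood
#' variable, 15 series in total.
#'
#' Conventions: the body-tail angle is taken at the tail base (shoulders
#' midpoint -> tail base -> tail middle), the mid-tail angle at the tail
#' middle, and the head-body angle at the shoulders midpoint (nose ->
#' shoulders midpoint -> hips midpoint). Body rotation is the signed angle
#' of the shoulders-to-hips axis against the image vertical, in
#' `[-180, 180)`. Torsion is the left shoulder-hip distance over the right.
#' Speed is the body-centre frame-to-frame displacement times the frame
#' rate (first frame set to 0). The rearing proxy flags frames where body
#' extension stays below `rear_frac` of its session median for at least
#' `rear_min_s` seconds while speed is below `rear_speed_max` cm/s.
#'
#' @param track A corrected, calibrated [pose_track()].
#' @param rear_frac Body-extension contraction fraction for the rearing
#'   proxy (default 0.6).
#' @param rear_min_s Minimum duration of a rearing epoch in seconds
#'   (default 0.25).
#' @param rear_speed_max Maximum speed during rearing in cm/s (default 2).
#'
#' @return A `kinematic_series`: a data.frame with a `frame` column and the
#'   15 variables of [KINEMATIC_VARIABLES] (distances cm, angles degrees,
#'   speed cm/s), with the frame rate in `attr(, "fps")`.
#' @export
compute_kinematics <- function(track, rear_frac = 0.6, rear_min_s = 0.25,
                               rear_speed_max = 2) {
  if (is.null(track$calibration))
    stop("track is not calibrated; run calibrate_arena() first")
  s <- track$calibration$cm_per_px
  n <- n_frames(track)

  sh_mid <- mid_xy(track, "shoulder_left", "shoulder_right")
  hip_mid <- mid_xy(track, "hip_left", "hip_right")
  ear_mid <- mid_xy(track, "ear_left", "ear_right")
  nose <- point_xy(track, "nose")
  centre <- point_xy(track, "body_centre")
  tail_base <- point_xy(track, "tail_base")
  tail_mid <- point_xy(track, "tail_middle")
  tail_end <- point_xy(track, "tail_end")

  dist_cm <- function(p, q) row_norm(p[, 1] - q[, 1], p[, 2] - q[, 2]) * s

  body_extension <- dist_cm(sh_mid, hip_mid)
  shoulder_distance <- dist_cm(point_xy(track, "shoulder_left"),
                               point_xy(track, "shoulder_right"))
  hip_distance <- dist_cm(point_xy(track, "hip_left"),
                          point_xy(track, "hip_right"))
  tailmid_to_centre <- dist_cm(tail_mid, centre)
  tail_extension <- dist_cm(tail_base, tail_end)
  head_extension <- dist_cm(nose, ear_mid)

  body_tail_angle <- angle_at_vertex(sh_mid, tail_base, tail_mid)
  mid_tail_angle <- angle_at_vertex(tail_base, tail_mid, tail_end)
  head_body_angle <- angle_at_vertex(nose, sh_mid, hip_mid)
  body_rotation <- signed_angle_to_vertical(hip_mid - sh_mid)

  box_centre <- matrix(track$calibration$centre_px, n, 2, byrow = TRUE)
  distance_to_box_centre <- dist_cm(centre, box_centre)

  body_torsion <- dist_cm(point_xy(track, "shoulder_left"),
                          point_xy(track, "hip_left")) /
    dist_cm(point_xy(track, "shoulder_right"),
            point_xy(track, "hip_right"))

  step <- row_norm(diff(centre[, 1]), diff(centre[, 2])) * s
  speed <- c(0, step) * track$fps

  jump_likelihood <- jump_likelihood_series(track)

  contracted <- body_extension < rear_frac * stats::median(body_extension)
  slow <- speed < rear_speed_max
  rearing <- as.numeric(sustained(contracted & slow,
                                  max(1L, round(rear_min_s * track$fps))))

  out <- data.frame(
    frame = seq_len(n) - 1L,
    body_extension = body_extension,
    shoulder_distance = shoulder_distance,
    hip_distance = hip_distance,
    tailmid_to_centre = tailmid_to_centre,
    tail_extension = tail_extension,
    head_extension = head_extension,
    body_tail_angle = body_tail_angle,
    mid_tail_angle = mid_tail_angle,
    head_body_angle = head_body_angle,
    body_rotation = body_rotation,
    distance_to_box_centre = distance_to_box_centre,
    body_torsion = body_torsion,
    speed = speed,
    rearing = rearing,
    jump_likelihood = jump_likelihood
  )
  attr(out, "fps") <- track$fps
  class(out) <- c("kinematic_series", "data.frame")
  out
}
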