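# Crafted pose tracks for unit tests. The template places the 11 animal
# points around given per-frame centres with a fixed heading; corners span
# a 400 px square in a 640x480 frame, giving 0.05 cm/px for a 20 cm arena.

TEST_CORNERS <- rbind(corner_tl = c(120, 40), corner_tr = c(520, 40),
                      corner_br = c(520, 440), corner_bl = c(120, 440))

# longitudinal/lateral offsets (px) of the animal points
TEST_OFFSETS <- matrix(c(
  70, 0,   50, 16,   50, -16,   30, 20,   30, -20,   0, 0,
  -30, 20, -30, -20, -50, 0,   -80, 0,  -110, 0
), ncol = 2, byrow = TRUE, dimnames = list(ANIMAL_POINTS, NULL))

template_track <- function(centres, heading = 0, lik = 1, fps = 40,
                           spine_scale = 1) {
  if (is.vector(centres)) centres <- matrix(centres, 1, 2)
  n <- nrow(centres)
  if (length(heading) == 1L) heading <- rep(heading, n)
  if (length(spine_scale) == 1L) spine_scale <- rep(spine_scale, n)
  x <- matrix(0, n, 15L, dimnames = list(NULL, ALL_POINTS))
  y <- x
  for (p in ANIMAL_POINTS) {
    lon <- TEST_OFFSETS[p, 1] * spine_scale
    lat <- TEST_OFFSETS[p, 2]
    x[, p] <- centres[, 1] + lon * cos(heading) - lat * sin(heading)
    y[, p] <- centres[, 2] + lon * sin(heading) + lat * cos(heading)
  }
  for (p in CORNER_POINTS) {
    x[, p] <- TEST_CORNERS[p, 1]
    y[, p] <- TEST_CORNERS[p, 2]
  }
  l <- matrix(lik, n, 15L, dimnames = list(NULL, ALL_POINTS))
  pose_track(x, y, l, fps = fps)
}

# a calibrated static track at the arena centre
static_track <- function(n = 100, fps = 40) {
  calibrate_arena(template_track(matrix(rep(c(320, 240), each = n), n, 2),
                                 fps = fps))
}

# minimal kinematic series carrying only what event detectors consume
speed_series <- function(speed, fps = 40) {
  out <- data.frame(frame = seq_along(speed) - 1L, speed = speed)
  attr(out, "fps") <- fps
  class(out) <- c("kinematic_series", "data.frame")
  out
}

# run the standard correction -> smoothing -> calibration chain on a
# generated session, protecting candidate jump windows as the pipeline does
process_session <- function(ses) {
  corr <- correct_coordinates(ses$track,
    protect_frames = candidate_jump_frames(ses$track))
  calibrate_arena(smooth_coordinates(corr))
}

# interval overlap matching with optional slack in frames
match_events <- function(a_on, a_off, b_on, b_off, slack = 0L) {
  vapply(seq_along(a_on), function(i)
    any(b_on <= a_off[i] + slack & b_off >= a_on[i] - slack), TRUE)
}
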