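#' Construct a pose track
#'
#' A `pose_track` holds per-frame x/y coordinates (pixels, image convention:
#' origin top-left, y increasing downward) and tracking likelihoods for a set
#' of named body points, together with the video frame rate and, once
#' [calibrate_arena()] has been applied, a pixel-to-centimetre calibration.
#'
#' @param x,y,likelihood Numeric matrices, frames x points, with identical
#'   dimnames; column names must cover [ALL_POINTS].
#' @param fps Frame rate in frames per second.
#' @param frame_px Integer vector `c(width, height)` of the video frame.
#' @param calibration Either `NULL` or a list with elements `cm_per_px`
#'   (scalar) and `centre_px` (length-2 numeric, arena centre).
#' @param replaced Optional logical matrix marking coordinates replaced by
#'   [correct_coordinates()].
#'
#' @return An object of class `pose_track`.
#' @seealso [read_pose_table()], [correct_coordinates()], [smooth_coordinates()]
#' @export
pose_track <- function(x, y, likelihood, fps, frame_px = c(640L, 480L),
                       calibration = NULL, replaced = NULL) {
  stopifnot(is.matrix(x), is.matrix(y), is.matrix(likelihood))
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(likelihood)))
    stop("x, y and likelihood must have identical dimensions")
  if (is.null(colnames(x))) stop("point columns must be named")
  missing <- setdiff(ALL_POINTS, colnames(x))
  if (length(missing))
    stop("missing bodypart: ", paste(missing, collapse = ", "))
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  bad <- likelihood < 0 | likelihood > 1
  if (any(bad, na.rm = TRUE)) stop("likelihood values must lie in [0, 1]")
  structure(
    list(x = x, y = y, likelihood = likelihood, fps = fps,
         frame_px = as.numeric(frame_px), calibration = calibration,
         replaced = replaced),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat("<pose_track> ", nrow(x$x), " frames, ", ncol(x$x), " points @ ",
      x$fps, " fps\n", sep = "")
  if (!is.null(x$calibration))
    cat("  calibrated: ", signif(x$calibration$cm_per_px, 4), " cm/px\n",
        sep = "")
  invisible(x)
}

#' @export
#' @rdname pose_track
n_frames <- function(track) nrow(track$x)

# x/y coordinates of one point as a 2-column matrix
point_xy <- function(track, point) {
  cbind(track$x[, point], track$y[, point])
}

# midpoint of two points, frames x 2
mid_xy <- function(track, p1, p2) {
  (point_xy(track, p1) + point_xy(track, p2)) / 2
}

# mean animal-point likelihood per frame: the "tracking confidence".
# Corners are static and excluded so dropouts are not diluted.
tracking_confidence <- function(track) {
  rowMeans(track$likelihood[, ANIMAL_POINTS, drop = FALSE])
}
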