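#' Detect withdrawal jumps
#'
#' A sequence of consecutive frames is considered a jump when the tracking
#' confidence (mean animal-point likelihood) drops below `conf_thresh` and
#' the speed around the loss of tracking exceeds `speed_thresh`. Candidate
#' low-confidence runs separated by less than `merge_gap_s` are merged, runs
#' shorter than `min_run` frames are discarded, and a candidate qualifies as
#' a jump iff the maximum speed within `window_s` of the run exceeds the
#' speed threshold. Detection uses the raw (pre-replacement) likelihoods,
#' which [correct_coordinates()] preserves.
#'
#' @param track A [pose_track()] (for the raw confidences).
#' @param kin The matching `kinematic_series` (for the calibrated speed).
#' @param conf_thresh Tracking-confidence threshold (default 0.50).
#' @param speed_thresh Speed threshold in cm/s (default 10).
#' @param window_s Half-width, in seconds, of the speed window around each
#'   low-confidence run (default 0.25).
#' @param merge_gap_s Runs closer than this (seconds) are merged before
#'   testing (default 0.125).
#' @param min_run Minimum run length in frames (default 2).
#'
#' @return A data.frame with one row per jump: `onset`, `offset` (frame
#'   indices, 1-based, inclusive), `onset_s`, `offset_s`, `peak_speed`
#'   (cm/s) and `min_confidence`.
#' @export
detect_jumps <- function(track, kin, conf_thresh = 0.50, speed_thresh = 10,
                         window_s = 0.25, merge_gap_s = 0.125, min_run = 2L) {
  empty <- data.frame(onset = integer(), offset = integer(),
                      onset_s = numeric(), offset_s = numeric(),
                      peak_speed = numeric(), min_confidence = numeric())
  n <- n_frames(track)
  if (n == 0L) return(empty)
  fps <- track$fps
  conf <- tracking_confidence(track)
  runs <- runs_of(conf < conf_thresh)
  if (!nrow(runs)) return(empty)

  # merge runs separated by short gaps
  gap_max <- merge_gap_s * fps
  if (nrow(runs) > 1L) {
    keep_start <- c(TRUE, runs$onset[-1L] - runs$offset[-nrow(runs)] - 1L >=
                      gap_max)
    grp <- cumsum(keep_start)
    runs <- data.frame(
      onset = tapply(runs$onset, grp, min),
      offset = tapply(runs$offset, grp, max)
    )
  }
  runs <- runs[runs$offset - runs$onset + 1L >= min_run, , drop = FALSE]
  if (!nrow(runs)) return(empty)

  w <- round(window_s * fps)
  speed <- kin$speed
  res <- lapply(seq_len(nrow(runs)), function(i) {
    lo <- max(1L, runs$onset[i] - w)
    hi <- min(n, runs$offset[i] + w)
    peak <- max(speed[lo:hi], na.rm = TRUE)
    if (peak <= speed_thresh) return(NULL)
    data.frame(onset = runs$onset[i], offset = runs$offset[i],
               onset_s = (runs$onset[i] - 1L) / fps,
               offset_s = (runs$offset[i] - 1L) / fps,
               peak_speed = peak,
               min_confidence = min(conf[runs$onset[i]:runs$offset[i]]))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

#' Frames inside candidate jump windows
#'
#' Runs of frames whose raw tracking confidence falls below `conf_thresh`,
#' padded by `pad_s` on each side. Used to exempt genuine mid-air frames
#' from outlier replacement in [correct_coordinates()]: the ballistic
#' displacement of a jump would otherwise be flagged as a tracking spike
#' and interpolated away, hiding the very speed signature that jump
#' detection relies on.
#'
#' @param track A [pose_track()] with raw likelihoods.
#' @param conf_thresh Tracking-confidence threshold (default 0.50).
#' @param pad_s Padding around each run, in seconds (default 0.25).
#' @return Integer vector of frame indices.
#' @export
candidate_jump_frames <- function(track, conf_thresh = 0.50, pad_s = 0.25) {
  runs <- runs_of(tracking_confidence(track) < conf_thresh)
  if (!nrow(runs)) return(integer())
  pad <- round(pad_s * track$fps)
  n <- n_frames(track)
  sort(unique(unlist(lapply(seq_len(nrow(runs)), function(i)
    max(1L, runs$onset[i] - pad):min(n, runs$offset[i] + pad)))))
}

#' Low-noise centroid speed for immobility scoring
#'
#' Per-frame speed of the whole-body centroid, computed as the mean of the
#' 11 animal points. Averaging the points reduces tracking jitter by
#' roughly the square root of their number, which keeps the apparent speed
#' of a stationary animal well below the immobility threshold while
#' leaving movement onsets and offsets sharp to one frame (no temporal
#' smoothing is applied).
#'
#' @param track A corrected, calibrated [pose_track()].
#' @return Numeric vector of speeds, cm/s, one per frame (first frame 0).
#' @export
immobility_speed <- function(track) {
  if (is.null(track$calibration))
    stop("track is not calibrated; run calibrate_arena() first")
  cx <- rowMeans(track$x[, ANIMAL_POINTS, drop = FALSE])
  cy <- rowMeans(track$y[, ANIMAL_POINTS, drop = FALSE])
  step <- row_norm(diff(cx), diff(cy))
  c(0, step) * track$fps * track$calibration$cm_per_px
}

#' Detect immobility bouts
#'
#' Maximal runs of frames with speed below `speed_thresh` lasting at least
#' `min_bout` seconds. Above-threshold interruptions shorter than
#' `min_gap_s` (single-frame tracking-noise glitches, brief twitches) do
#' not break a bout.
#'
#' @param speed Numeric speed series in cm/s (e.g. [immobility_speed()]),
#'   or a `kinematic_series`, in which case its `speed` column and fps
#'   attribute are used.
#' @param fps Frame rate (ignored when `speed` is a `kinematic_series`).
#' @param speed_thresh Immobility threshold in cm/s (default 4, above the
#'   tracking-noise floor of 40 fps markerless pose data and below any
#'   true locomotion).
#' @param min_bout Minimum bout duration in seconds (default 2).
#' @param min_gap_s Above-threshold interruptions shorter than this do not
#'   break a bout (default 0.25 s; 0 disables gap closing).
#' @param exclude Optional data.frame with `onset`/`offset` frame columns
#'   (e.g. detected jumps): those windows always count as movement and
#'   always break a bout, however brief.
#'
#' @return A data.frame with one row per bout: `onset`, `offset` (frames),
#'   `onset_s`, `offset_s`, `duration_s`; total immobility time in
#'   `attr(, "total_s")`.
#' @export
detect_immobility <- function(speed, fps = NULL, speed_thresh = 4,
                              min_bout = 2, min_gap_s = 0.25,
                              exclude = NULL) {
  if (inherits(speed, "kinematic_series")) {
    fps <- attr(speed, "fps")
    speed <- speed$speed
  }
  if (is.null(fps)) stop("fps required when speed is a plain vector")
  still <- speed < speed_thresh
  hard_move <- rep(FALSE, length(still))
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude)))
      hard_move[exclude$onset[i]:exclude$offset[i]] <- TRUE
    still <- still & !hard_move
  }
  if (min_gap_s > 0) {
    gaps <- runs_of(!still)
    short <- gaps[gaps$offset - gaps$onset + 1L < min_gap_s * fps &
                    gaps$onset > 1L & gaps$offset < length(still), ,
                  drop = FALSE]
    if (nrow(short))
      for (i in seq_len(nrow(short))) {
        idx <- short$onset[i]:short$offset[i]
        still[idx] <- !hard_move[idx]
      }
  }
  runs <- runs_of(still)
  dur <- (runs$offset - runs$onset + 1L) / fps
  keep <- dur >= min_bout
  out <- data.frame(onset = runs$onset[keep], offset = runs$offset[keep],
                    onset_s = (runs$onset[keep] - 1L) / fps,
                    offset_s = (runs$offset[keep] - 1L) / fps,
                    duration_s = dur[keep])
  attr(out, "total_s") <- sum(out$duration_s)
  out
}

#' Distance travelled
#'
#' Sum of body-centre frame-to-frame displacements, in metres. Frames
#' inside detected jump windows are excluded because tracking is invalid
#' there.
#'
#' @param kin A `kinematic_series`.
#' @param jumps Optional jump table from [detect_jumps()]; displacements on
#'   frames within `[onset, offset]` of any jump are dropped.
#' @return Distance in metres.
#' @export
distance_travelled <- function(kin, jumps = NULL) {
  fps <- attr(kin, "fps")
  step_cm <- kin$speed / fps
  if (!is.null(jumps) && nrow(jumps)) {
    drop <- unlist(lapply(seq_len(nrow(jumps)), function(i)
      jumps$onset[i]:jumps$offset[i]))
    step_cm[drop] <- 0
  }
  sum(step_cm) / 100
}

#' Event summary for a session
#'
#' Convenience wrapper bundling jumps, immobility bouts and totals.
#'
#' @param track Corrected, calibrated [pose_track()].
#' @param kin Matching `kinematic_series`.
#' @param ... Passed on to [detect_jumps()].
#' @param immobility_thresh Speed threshold for [detect_immobility()]
#'   (cm/s).
#' @return A list of class `event_table`: `jumps`, `immobility`, and
#'   `totals` (jump count, immobility seconds, distance metres).
#' @export
event_table <- function(track, kin, immobility_thresh = 4, ...) {
  jumps <- detect_jumps(track, kin, ...)
  imm <- detect_immobility(immobility_speed(track), fps = track$fps,
                           speed_thresh = immobility_thresh,
                           exclude = jumps)
  structure(list(
    jumps = jumps,
    immobility = imm,
    totals = list(jump_count = nrow(jumps),
                  immobility_s = attr(imm, "total_s"),
                  distance_m = distance_travelled(kin, jumps))
  ), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", x$totals$jump_count, " jumps, ",
      round(x$totals$immobility_s, 1), " s immobile, ",
      round(x$totals$distance_m, 2), " m travelled\n", sep = "")
  invisible(x)
}

#' Place-preference / place-aversion score
#'
#' Time spent in the target compartment divided by the time spent in both
#' choice compartments; corridor time never enters the denominator.
#'
#' @param occupancy Either a character/factor vector giving the compartment
#'   of each frame, or a named numeric vector of dwell times per
#'   compartment.
#' @param target Name of the target (drug-paired or stimulated)
#'   compartment.
#' @param exclude Compartments excluded from the denominator (default
#'   `"corridor"`).
#' @return Score in `[0, 1]`.
#' @export
place_preference_score <- function(occupancy, target, exclude = "corridor") {
  if (is.numeric(occupancy)) {
    times <- occupancy
  } else {
    times <- table(as.character(occupancy))
    times <- stats::setNames(as.numeric(times), names(times))
  }
  if (!target %in% names(times)) times[target] <- 0
  comps <- setdiff(names(times), exclude)
  if (!target %in% comps) stop("target compartment is excluded")
  t_target <- times[[target]]
  t_both <- sum(times[comps])
  if (t_both <= 0) stop("undefined score: no time spent in either compartment")
  unname(t_target / t_both)
}
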