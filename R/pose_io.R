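#' Read a DLC-style pose table
#'
#' Parses the three-row-header CSV layout produced by markerless pose
#' estimation suites: row 1 `scorer`, row 2 `bodyparts`, row 3 `coords`
#' (x / y / likelihood triplets), then one row per frame with the frame
#' index in the first column.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate of the source video (frames/s, default 40).
#' @param frame_px Video frame size `c(width, height)` in pixels.
#'
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, fps = 40, frame_px = c(640L, 480L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 4L)
    stop("malformed pose table (need 3 header rows + data): ", path)
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  tags <- vapply(hdr, `[`, "", 1L)
  if (!identical(tolower(tags), c("scorer", "bodyparts", "coords")))
    stop("malformed header: expected rows 'scorer', 'bodyparts', 'coords', ",
         "got '", paste(tags, collapse = "', '"), "' (lines 1-3)")
  bodyparts <- hdr[[2]][-1L]
  coords <- hdr[[3]][-1L]
  if (length(bodyparts) != length(coords))
    stop("malformed header: bodyparts row has ", length(bodyparts),
         " columns but coords row has ", length(coords), " (lines 2-3)")
  pts <- unique(bodyparts)
  for (p in pts) {
    got <- sort(coords[bodyparts == p])
    if (!identical(got, c("likelihood", "x", "y")))
      stop("bodypart '", p, "' must have x, y and likelihood columns (line 3)")
  }
  missing <- setdiff(ALL_POINTS, pts)
  if (length(missing))
    stop("missing bodypart: ", paste(missing, collapse = ", "))

  ncol_expect <- length(bodyparts) + 1L
  data <- lines[-(1:3)]
  data <- data[nzchar(data)]
  rows <- strsplit(data, ",", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != ncol_expect))
    stop("inconsistent row length at line ",
         3L + which(lens != ncol_expect)[1L],
         " (expected ", ncol_expect, " fields, found ",
         lens[lens != ncol_expect][1L], ")")
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  vals <- m[, -1L, drop = FALSE]

  take <- function(coord) {
    out <- vals[, coords == coord, drop = FALSE]
    colnames(out) <- bodyparts[coords == coord]
    out[, ALL_POINTS, drop = FALSE]
  }
  pose_track(take("x"), take("y"), take("likelihood"),
             fps = fps, frame_px = frame_px)
}

#' Write a pose track as a DLC-style CSV
#'
#' @param track A [pose_track()].
#' @param path Output path.
#' @param scorer Scorer tag written in the first header row.
#' @param digits Number of significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path, scorer = "opiometrics",
                             digits = 10) {
  pts <- colnames(track$x)
  hdr1 <- paste(c("scorer", rep(scorer, 3L * length(pts))), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(pts, each = 3L)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(pts))),
                collapse = ",")
  n <- n_frames(track)
  body <- matrix(0, n, 3L * length(pts))
  body[, seq(1L, ncol(body), 3L)] <- track$x
  body[, seq(2L, ncol(body), 3L)] <- track$y
  body[, seq(3L, ncol(body), 3L)] <- track$likelihood
  rows <- apply(body, 1L, function(r)
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(c(hdr1, hdr2, hdr3,
               paste(seq_len(n) - 1L, rows, sep = ",")), path)
  invisible(path)
}

# robust spike test: a frame is a tracking glitch when the steps into and
# out of it both exceed k robust SDs of that point's per-frame
# displacement AND the point returns (net displacement across the frame
# below the same threshold). The return condition separates glitches from
# genuinely fast motion such as the tail whipping around during a turn.
speed_outlier_mask <- function(px, py, k) {
  n <- length(px)
  if (n < 3L) return(rep(FALSE, n))
  d <- row_norm(diff(px), diff(py))          # length n-1, d[i] = step i -> i+1
  s <- stats::mad(d, constant = 1.4826)
  if (!is.finite(s) || s <= 0) return(rep(FALSE, n))
  thr <- k * s
  big <- d > thr
  net <- row_norm(px[3:n] - px[1:(n - 2L)],  # i-1 -> i+1, for i = 2..n-1
                  py[3:n] - py[1:(n - 2L)])
  out <- rep(FALSE, n)
  out[2:(n - 1L)] <- big[1:(n - 2L)] & big[2:(n - 1L)] & net < thr
  out
}

#' Correct low-confidence and outlier coordinates
#'
#' Replaces, for each body point independently, the frames whose tracking
#' likelihood falls below `conf_thresh`, whose position leaves the arena
#' bounding box by more than `pos_margin_px`, or which form a displacement
#' spike (step in and step out both above `speed_k` robust SDs of that
#' point's per-frame displacement), with values from a natural cubic
#' interpolation over the remaining valid frames. Runs of invalid frames at
#' the sequence edges are filled with the nearest valid value rather than
#' extrapolated. Likelihoods are never modified, so downstream jump
#' detection still sees the raw confidence.
#'
#' @param track A [pose_track()].
#' @param conf_thresh Likelihood threshold below which a frame is replaced
#'   (default 0.05).
#' @param speed_k Multiplier on the MAD-based robust SD of displacements for
#'   the spike test (default 6).
#' @param pos_margin_px Slack, in pixels, beyond the arena bounding box
#'   before a position counts as an outlier (default 5).
#' @param protect_frames Optional integer vector of frame indices exempt
#'   from outlier replacement (e.g. frames inside detected jumps, where the
#'   animal genuinely leaves the frame).
#'
#' @return The corrected [pose_track()], with a logical `replaced` matrix
#'   (frames x points) marking every replaced coordinate.
#' @export
correct_coordinates <- function(track, conf_thresh = 0.05, speed_k = 6,
                                pos_margin_px = 5, protect_frames = NULL) {
  n <- n_frames(track)
  pts <- colnames(track$x)

  # arena bounding box from the corner points if present, else frame extent
  cx <- track$x[, CORNER_POINTS, drop = FALSE]
  cy <- track$y[, CORNER_POINTS, drop = FALSE]
  bbox <- c(xmin = min(cx), xmax = max(cx), ymin = min(cy), ymax = max(cy))

  x <- track$x; y <- track$y
  replaced <- matrix(FALSE, n, length(pts), dimnames = dimnames(x))
  protect <- rep(FALSE, n)
  if (!is.null(protect_frames)) protect[protect_frames] <- TRUE

  for (p in pts) {
    low <- track$likelihood[, p] < conf_thresh
    outside <- x[, p] < bbox["xmin"] - pos_margin_px |
      x[, p] > bbox["xmax"] + pos_margin_px |
      y[, p] < bbox["ymin"] - pos_margin_px |
      y[, p] > bbox["ymax"] + pos_margin_px
    spike <- speed_outlier_mask(x[, p], y[, p], speed_k)
    bad <- low | ((outside | spike) & !protect)
    if (!any(bad)) next
    good <- which(!bad)
    if (length(good) < 4L)
      stop("uncorrectable track: bodypart '", p, "' has fewer than 4 valid frames")
    idx <- which(bad)
    interior <- idx[idx > min(good) & idx < max(good)]
    if (length(interior)) {
      x[interior, p] <- stats::spline(good, x[good, p], xout = interior,
                                      method = "natural")$y
      y[interior, p] <- stats::spline(good, y[good, p], xout = interior,
                                      method = "natural")$y
    }
    lead <- idx[idx < min(good)]
    if (length(lead)) {
      x[lead, p] <- x[min(good), p]; y[lead, p] <- y[min(good), p]
    }
    trail <- idx[idx > max(good)]
    if (length(trail)) {
      x[trail, p] <- x[max(good), p]; y[trail, p] <- y[max(good), p]
    }
    replaced[idx, p] <- TRUE
  }
  pose_track(x, y, track$likelihood, fps = track$fps,
             frame_px = track$frame_px, calibration = track$calibration,
             replaced = replaced)
}

# centred moving average with shrinking windows at the edges
moving_average <- function(v, width) {
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  n <- length(v)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth coordinates with a moving-average filter
#'
#' Each coordinate series is convolved with a centred uniform kernel of the
#' given width (default 5 frames); at the series edges the window shrinks
#' symmetrically. Likelihoods are left untouched.
#'
#' @param track A [pose_track()].
#' @param width Odd window width in frames (default 5).
#' @return The smoothed [pose_track()].
#' @export
smooth_coordinates <- function(track, width = 5) {
  if (width < 1 || width %% 2 == 0)
    stop("width must be an odd positive integer")
  x <- apply(track$x, 2L, moving_average, width = width)
  y <- apply(track$y, 2L, moving_average, width = width)
  dimnames(x) <- dimnames(track$x); dimnames(y) <- dimnames(track$y)
  pose_track(x, y, track$likelihood, fps = track$fps,
             frame_px = track$frame_px, calibration = track$calibration,
             replaced = track$replaced)
}

#' Calibrate the arena scale from the tracked corners
#'
#' The pixel-to-centimetre scale is `arena_cm` divided by the median
#' corner-to-corner side length (in pixels) of the arena, computed from the
#' median position of each corner across frames; the arena centre is the
#' centroid of the four median corner positions.
#'
#' @param track A [pose_track()].
#' @param arena_cm Side length of the (square) arena in cm (default 20).
#' @return The [pose_track()] with its `calibration` field set.
#' @export
calibrate_arena <- function(track, arena_cm = 20) {
  corners <- vapply(CORNER_POINTS, function(p)
    c(stats::median(track$x[, p]), stats::median(track$y[, p])),
    numeric(2))
  # sides in TL -> TR -> BR -> BL order
  ord <- corners[, CORNER_POINTS]
  sides <- vapply(1:4, function(i) {
    j <- if (i == 4L) 1L else i + 1L
    sqrt(sum((ord[, i] - ord[, j])^2))
  }, 0)
  side_px <- stats::median(sides)
  if (!is.finite(side_px) || side_px <= 0)
    stop("degenerate corners: arena side length is zero")
  track$calibration <- list(
    cm_per_px = arena_cm / side_px,
    centre_px = rowMeans(ord),
    arena_cm = arena_cm
  )
  track
}
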