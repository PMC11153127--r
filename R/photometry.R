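#' Construct a photometry recording
#'
#' Container for a two-channel fibre-photometry session: time stamps, the
#' calcium-dependent 470 nm channel, the calcium-independent (isosbestic)
#' 405 nm control channel, optional named event markers, and - once
#' [fit_isosbestic()] / [compute_dff()] have run - the fitted control and
#' the dF/F trace.
#'
#' @param t Time stamps in seconds (strictly increasing).
#' @param f470,f405 Fluorescence of the two channels (arbitrary units).
#' @param baseline_window Length-2 numeric, `c(start, end)` seconds of the
#'   pre-injection baseline (default first 300 s, i.e. 5 min).
#' @param markers Named list of event times in seconds.
#' @return An object of class `photometry_recording`.
#' @export
photometry_recording <- function(t, f470, f405,
                                 baseline_window = c(0, 300),
                                 markers = list()) {
  if (length(t) != length(f470) || length(t) != length(f405))
    stop("t, f470 and f405 must have equal length")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (baseline_window[1] < t[1] - 1e-9 ||
      baseline_window[2] > t[length(t)] + 1e-9)
    stop("baseline_window must lie within the recording")
  structure(list(t = t, f470 = f470, f405 = f405,
                 baseline_window = baseline_window, markers = markers,
                 fitted405 = NULL, dff = NULL),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat("<photometry_recording> ", length(x$t), " samples, ",
      round(diff(range(x$t)), 1), " s",
      if (!is.null(x$dff)) ", dF/F computed", "\n", sep = "")
  invisible(x)
}

#' Fit the isosbestic control channel
#'
#' The 405 nm signal is linearly regressed against the 470 nm signal over
#' the baseline window only (least squares `f470 ~ a + b * f405`), and the
#' fitted line is applied to the 405 nm channel over the full recording,
#' yielding a motion- and bleaching-matched control scaled to the 470 nm
#' signal.
#'
#' @param rec A [photometry_recording()].
#' @param baseline_window Optional override of the recording's baseline
#'   window, `c(start, end)` in seconds.
#' @return The recording with `fitted405` filled in and the fit
#'   coefficients in `attr(rec$fitted405, "coef")`.
#' @export
fit_isosbestic <- function(rec, baseline_window = NULL) {
  bw <- baseline_window %||% rec$baseline_window
  sel <- rec$t >= bw[1] & rec$t <= bw[2]
  if (sum(sel) < 2L) stop("baseline window contains fewer than 2 samples")
  if (stats::sd(rec$f405[sel]) == 0)
    stop("singular fit: f405 is constant on the baseline window")
  fit <- stats::lm.fit(cbind(1, rec$f405[sel]), rec$f470[sel])
  ab <- fit$coefficients
  fitted405 <- ab[1] + ab[2] * rec$f405
  attr(fitted405, "coef") <- c(intercept = unname(ab[1]),
                               slope = unname(ab[2]))
  rec$fitted405 <- fitted405
  rec$baseline_window <- bw
  rec
}

#' Compute dF/F
#'
#' `dF/F = (f470 - fitted405) / fitted405`, elementwise. Samples where the
#' fitted control is non-positive are masked (`NA`) and their count
#' reported in `attr(dff, "n_masked")`.
#'
#' @param rec A [photometry_recording()] after [fit_isosbestic()].
#' @return The recording with its `dff` field filled in.
#' @export
compute_dff <- function(rec) {
  if (is.null(rec$fitted405))
    stop("fitted405 missing; run fit_isosbestic() first")
  f <- as.numeric(rec$fitted405)
  dff <- (rec$f470 - f) / f
  bad <- f <= 0
  dff[bad] <- NA_real_
  attr(dff, "n_masked") <- sum(bad)
  rec$dff <- dff
  rec
}

#' Bin a dF/F trace into fixed time bins
#'
#' @param dff Numeric dF/F series.
#' @param t Time stamps in seconds (same length), or `NULL` with `fps`
#'   giving a uniform rate starting at 0.
#' @param bin_s Bin width in seconds (default 10).
#' @param fps Sampling rate, used when `t` is `NULL`.
#' @return data.frame with `bin_start`, `bin_mid`, `mean`, `n`, and
#'   `partial` (TRUE for a trailing incomplete bin).
#' @export
bin_dff <- function(dff, t = NULL, bin_s = 10, fps = NULL) {
  if (bin_s <= 0) stop("bin_s must be positive")
  if (is.null(t)) {
    if (is.null(fps)) stop("provide t or fps")
    t <- (seq_along(dff) - 1L) / fps
  }
  idx <- floor((t - t[1]) / bin_s)
  dt <- stats::median(diff(t))
  full_n <- round(bin_s / dt)
  agg <- tapply(dff, idx, mean, na.rm = TRUE)
  cnt <- tapply(dff, idx, length)
  bins <- as.integer(names(agg))
  data.frame(bin_start = t[1] + bins * bin_s,
             bin_mid = t[1] + (bins + 0.5) * bin_s,
             mean = as.numeric(agg),
             n = as.integer(cnt),
             partial = as.integer(cnt) < full_n)
}

#' Topographic prominence of local maxima
#'
#' For each strict local maximum, the prominence is its height above the
#' higher of the two reference saddles: on each side, the minimum of the
#' signal between the peak and the nearest sample exceeding the peak's
#' height (or the series end if none does).
#'
#' @param x Numeric series (NAs treated as -Inf).
#' @return data.frame with `index`, `height`, `prominence`.
#' @export
peak_prominences <- function(x) {
  x0 <- x
  x0[is.na(x0)] <- -Inf
  n <- length(x0)
  if (n < 3L)
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  d <- diff(x0)
  # strict local maxima; for flat tops, take the first sample of the plateau
  rising <- d > 0
  falling <- d < 0
  is_peak <- logical(n)
  last_rise <- FALSE
  for (i in seq_len(n - 1L)) {
    if (rising[i]) last_rise <- TRUE
    if (falling[i]) {
      if (last_rise) is_peak[i] <- TRUE
      last_rise <- FALSE
    }
  }
  pk <- which(is_peak)
  prom <- vapply(pk, function(i) {
    h <- x0[i]
    lmin <- h; j <- i - 1L
    while (j >= 1L && x0[j] <= h) { if (x0[j] < lmin) lmin <- x0[j]; j <- j - 1L }
    if (j < 1L) lmin <- min(x0[1:i])
    rmin <- h; j <- i + 1L
    while (j <= n && x0[j] <= h) { if (x0[j] < rmin) rmin <- x0[j]; j <- j + 1L }
    if (j > n) rmin <- min(x0[i:n])
    h - max(lmin, rmin)
  }, 0)
  data.frame(index = pk, height = x[pk], prominence = prom)
}

#' Detect calcium transients
#'
#' Local maxima of the dF/F trace whose topographic prominence exceeds
#' `k` standard deviations of the dF/F during the baseline window. Peaks
#' closer together than `min_sep_s` are resolved in favour of the more
#' prominent one.
#'
#' @param rec A [photometry_recording()] with `dff` computed, or a plain
#'   numeric dff series (then supply `t` and `baseline_window`).
#' @param t,baseline_window Used only when `rec` is a plain vector.
#' @param k Prominence threshold in baseline SDs (default 2).
#' @param min_sep_s Minimum separation between reported peaks in seconds
#'   (default 0.5).
#' @return data.frame of class `transient_set`: `time`, `height`,
#'   `prominence`; baseline SD in `attr(, "baseline_sd")`.
#' @export
detect_transients <- function(rec, t = NULL, baseline_window = NULL,
                              k = 2, min_sep_s = 0.5) {
  if (inherits(rec, "photometry_recording")) {
    dff <- rec$dff
    if (is.null(dff)) stop("dff missing; run compute_dff() first")
    t <- rec$t
    baseline_window <- baseline_window %||% rec$baseline_window
  } else {
    dff <- rec
    if (is.null(t) || is.null(baseline_window))
      stop("supply t and baseline_window with a plain dff vector")
  }
  sel <- t >= baseline_window[1] & t <= baseline_window[2]
  sd0 <- stats::sd(dff[sel], na.rm = TRUE)
  if (!is.finite(sd0)) stop("baseline SD not computable")
  pks <- peak_prominences(dff)
  pks <- pks[pks$prominence > k * sd0, , drop = FALSE]
  # enforce minimum separation, keeping the more prominent peak
  if (nrow(pks) > 1L && min_sep_s > 0) {
    ord <- order(-pks$prominence)
    keep <- logical(nrow(pks))
    taken <- numeric(0)
    for (i in ord) {
      ti <- t[pks$index[i]]
      if (!length(taken) || min(abs(taken - ti)) >= min_sep_s) {
        keep[i] <- TRUE
        taken <- c(taken, ti)
      }
    }
    pks <- pks[keep, , drop = FALSE]
    pks <- pks[order(pks$index), , drop = FALSE]
  }
  out <- data.frame(time = t[pks$index], height = pks$height,
                    prominence = pks$prominence)
  attr(out, "baseline_sd") <- sd0
  class(out) <- c("transient_set", "data.frame")
  out
}

#' Area under the dF/F curve
#'
#' Trapezoidal integral of the dF/F trace over a time window, at the native
#' sampling rate.
#'
#' @param dff Numeric dF/F series.
#' @param t Time stamps in seconds.
#' @param window Length-2 numeric, `c(start, end)` seconds.
#' @return Area in dF/F x seconds.
#' @export
compute_auc <- function(dff, t, window) {
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 2L) stop("empty AUC window")
  pracma::trapz(t[sel], dff[sel])
}

#' Normalize an injection-evoked AUC to the apomorphine response
#'
#' To account for individual sensor-expression levels, the drug-evoked AUC
#' is referenced to the AUC evoked by apomorphine in the same animal. Both
#' orientations of the ratio are returned, explicitly labelled.
#'
#' @param auc_fentanyl AUC evoked by the drug injection.
#' @param auc_apomorphine AUC evoked by apomorphine.
#' @return Named list: `apo_over_fent` and `fent_over_apo`.
#' @export
normalize_auc <- function(auc_fentanyl, auc_apomorphine) {
  if (auc_fentanyl == 0) stop("zero fentanyl AUC: ratio undefined")
  if (auc_apomorphine == 0) warning("zero apomorphine AUC")
  list(apo_over_fent = auc_apomorphine / auc_fentanyl,
       fent_over_apo = if (auc_apomorphine != 0)
         auc_fentanyl / auc_apomorphine else NA_real_)
}

#' Peri-event average of a dF/F trace
#'
#' Extracts, for each event, the dF/F segment in a window around the event
#' and averages across events. Sampling is assumed uniform; events whose
#' window is clipped by the recording edges are dropped and counted.
#'
#' @param dff Numeric dF/F series.
#' @param t Time stamps in seconds (uniform sampling).
#' @param event_times Event times in seconds.
#' @param window Length-2 numeric `c(-pre, +post)` in seconds (default
#'   `c(-5, 10)`).
#' @return List: `offset_s` (sample offsets), `trials` (events x samples
#'   matrix), `mean` (average trace), `n_events`, `n_dropped`.
#' @export
peri_event_average <- function(dff, t, event_times, window = c(-5, 10)) {
  dt <- stats::median(diff(t))
  pre <- round(-window[1] / dt)
  post <- round(window[2] / dt)
  idx0 <- vapply(event_times, function(e) which.min(abs(t - e)), 0L)
  ok <- idx0 - pre >= 1L & idx0 + post <= length(dff)
  if (!any(ok)) stop("no usable events: all windows clipped by recording edges")
  rows <- lapply(idx0[ok], function(i) dff[(i - pre):(i + post)])
  trials <- do.call(rbind, rows)
  list(offset_s = seq(-pre, post) * dt,
       trials = trials,
       mean = colMeans(trials),
       n_events = sum(ok),
       n_dropped = sum(!ok))
}
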