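#' Parameter-recovery study for the dose-response fit
#'
#' Simulates replicate occlusion experiments from a known log-dose 4PL
#' (per-subject responses, multiplicative noise), refits each, and
#' summarises the recovered IC50 and Hill coefficient by their medians.
#'
#' @param ic50,hill Generating parameters (doses and IC50 in µg/kg).
#' @param doses Dose schedule in µg/kg; zero doses (saline) are carried in
#'   the tables and excluded from the fits as usual.
#' @param n_subjects Animals per replicate.
#' @param n_replicates Number of simulated experiments (default 200).
#' @param cv Multiplicative noise CV (default 0.1).
#' @param top,bottom Generating asymptotes (default 1 and 0: rates as
#'   fraction of baseline).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List: `ic50_median`, `hill_median`, `ic50_rel_err`,
#'   `hill_rel_err` (relative to the generating values), `n_converged`.
#' @export
recover_dose_response <- function(ic50, hill, doses, n_subjects,
                                  n_replicates = 200, cv = 0.1,
                                  top = 1, bottom = 0, seed = 1) {
  ic <- hl <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    tab <- gen_dose_response(doses = doses, n_subjects = n_subjects,
                             top = top, bottom = bottom, ic50 = ic50,
                             hill = hill, cv = cv, seed = seed + r)
    fit <- fit_logistic4(tab, seed = seed + r)
    if (fit$converged) {
      ic[r] <- fit$estimates[["ic50"]]
      hl[r] <- fit$estimates[["hill"]]
    }
  }
  im <- stats::median(ic, na.rm = TRUE)
  hm <- stats::median(hl, na.rm = TRUE)
  list(ic50_median = im, hill_median = hm,
       ic50_rel_err = abs(im / ic50 - 1),
       hill_rel_err = abs(hm / hill - 1),
       n_converged = sum(!is.na(ic)))
}

#' Jump-detector performance on synthetic sessions with ground truth
#'
#' Generates withdrawal-like pose sessions, runs the full processing chain
#' (candidate-window protection, correction, smoothing, calibration,
#' kinematics, detection at the standard thresholds) and scores detected
#' jumps against the generator's ground truth by interval overlap.
#'
#' @param n_sessions Number of sessions (default 20).
#' @param duration_s Session length (default 600 s).
#' @param seed Base seed; session i uses `seed + i`.
#' @param slack_s Matching slack around each interval (default 0.25 s).
#' @param ... Further arguments to [pose_scenario()].
#' @return List: `recall`, `precision`, `n_true`, `n_detected`.
#' @export
jump_detection_performance <- function(n_sessions = 20, duration_s = 600,
                                       seed = 1, slack_s = 0.25, ...) {
  tp_t <- fn <- fp <- 0L
  for (i in seq_len(n_sessions)) {
    ses <- gen_pose_session(pose_scenario(duration_s = duration_s,
                                          seed = seed + i, ...))
    corr <- correct_coordinates(ses$track,
      protect_frames = candidate_jump_frames(ses$track))
    cal <- calibrate_arena(smooth_coordinates(corr))
    kin <- compute_kinematics(cal)
    det <- detect_jumps(cal, kin)
    tj <- ses$truth$jumps
    slack <- round(slack_s * ses$track$fps)
    hit_t <- vapply(seq_len(nrow(tj)), function(k)
      any(det$onset <= tj$offset[k] + slack &
            det$offset >= tj$onset[k] - slack), TRUE)
    hit_d <- vapply(seq_len(nrow(det)), function(k)
      any(tj$onset <= det$offset[k] + slack &
            tj$offset >= det$onset[k] - slack), TRUE)
    tp_t <- tp_t + sum(hit_t); fn <- fn + sum(!hit_t)
    fp <- fp + sum(!hit_d)
  }
  list(recall = tp_t / (tp_t + fn), precision = tp_t / (tp_t + fp),
       n_true = tp_t + fn, n_detected = tp_t + fp)
}

#' Transient-detector performance on synthetic recordings
#'
#' Generates photometry sessions at the default study conditions, runs the
#' isosbestic correction and prominence-based detection, and scores
#' detected peaks against the generated transient times.
#'
#' @param n_sessions Number of recordings (default 20).
#' @param seed Base seed.
#' @param match_tol_s Peak-time matching tolerance (default 0.3 s).
#' @param ... Further arguments to [photometry_scenario()].
#' @return List: `recall`, `precision`, `amplitude_sd_ratio` (kernel
#'   amplitude over the mean baseline SD, the effect size the detector
#'   faces), `n_true`, `n_detected`.
#' @export
transient_detection_performance <- function(n_sessions = 20, seed = 1,
                                            match_tol_s = 0.3, ...) {
  tp <- fn <- fp <- 0L
  sds <- amps <- numeric(n_sessions)
  for (i in seq_len(n_sessions)) {
    ses <- gen_photometry_session(photometry_scenario(seed = seed + i, ...))
    rec <- compute_dff(fit_isosbestic(ses$recording))
    tr <- detect_transients(rec)
    truth <- ses$truth
    sds[i] <- attr(tr, "baseline_sd")
    amps[i] <- ses$scenario$transient_kernel[["amplitude"]]
    hit_t <- vapply(truth$peak_s, function(p)
      any(abs(tr$time - p) <= match_tol_s), TRUE)
    hit_d <- vapply(tr$time, function(p)
      any(abs(truth$peak_s - p) <= match_tol_s), TRUE)
    tp <- tp + sum(hit_t); fn <- fn + sum(!hit_t); fp <- fp + sum(!hit_d)
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       amplitude_sd_ratio = mean(amps / sds),
       n_true = tp + fn, n_detected = tp + fp)
}

#' Residual dF/F after correcting a transient-free recording
#'
#' On a null synthetic recording (shared motion artifact and drift, no
#' transients), compares the RMS of the corrected dF/F with the RMS of the
#' naively normalized 470 nm channel, `(f470 - mean) / mean`: the ratio
#' measures how much of the nuisance variation the isosbestic regression
#' removes.
#'
#' @param seed Scenario seed.
#' @param ... Further arguments to [photometry_scenario()].
#' @return List: `rms_ratio`, `rms_dff`, `rms_uncorrected`.
#' @export
dff_null_rms_ratio <- function(seed = 1, ...) {
  ses <- gen_photometry_session(photometry_scenario(transient_rate = 0,
                                                    seed = seed, ...))
  rec <- compute_dff(fit_isosbestic(ses$recording))
  rms <- function(v) sqrt(mean(v^2))
  unc <- (rec$f470 - mean(rec$f470)) / mean(rec$f470)
  list(rms_ratio = rms(rec$dff) / rms(unc),
       rms_dff = rms(rec$dff), rms_uncorrected = rms(unc))
}

#' Exactness of the isosbestic regression on affine channels
#'
#' Builds a control channel with drift and oscillation, an exactly affine
#' 470 nm channel (`f470 = slope * f405 + intercept`), fits the baseline
#' regression and reports the absolute coefficient errors.
#'
#' @param intercept,slope The affine relation used (defaults 3 and 2).
#' @return Named numeric: `intercept_error`, `slope_error`.
#' @export
isosbestic_affine_error <- function(intercept = 3, slope = 2) {
  t <- seq(0, 600, by = 0.05)
  f405 <- 100 + 5 * exp(-t / 600) + sin(t / 7)
  rec <- fit_isosbestic(photometry_recording(t, slope * f405 + intercept,
                                             f405, c(0, 300)))
  cf <- attr(rec$fitted405, "coef")
  c(intercept_error = abs(unname(cf["intercept"]) - intercept),
    slope_error = abs(unname(cf["slope"]) - slope))
}

# speed series of one generated animal for classification studies
classification_series <- function(duration_s, effect_size, seed) {
  ses <- gen_pose_session(pose_scenario(duration_s = duration_s,
                                        jump_rate = 0,
                                        effect_size = effect_size,
                                        seed = seed))
  kin <- compute_kinematics(calibrate_arena(ses$track))
  kin$speed
}

#' Permutation-test calibration under the null
#'
#' Generates label-independent datasets (two groups drawn from identical
#' scenarios, `effect_size = 0`), runs the full feature extraction,
#' cross-validation and label-shuffling permutation test on each, and
#' reports the fraction of datasets with p < 0.05 — which should match the
#' nominal level for a calibrated test.
#'
#' @param n_datasets Number of simulated datasets (default 200).
#' @param n_per_group Animals per group (default 20).
#' @param duration_s Session length per animal (default 30 s; the speed
#'   series is the classified variable).
#' @param n_shuffles Shuffles per permutation test (default 200).
#' @param repeats CV repeats within each test (default 1 at this scale).
#' @param seed Base seed.
#' @return List: `fpr` (fraction with p < 0.05), `p_values`,
#'   `balanced_accuracies`.
#' @export
null_classification_calibration <- function(n_datasets = 200,
                                            n_per_group = 20,
                                            duration_s = 30,
                                            n_shuffles = 200,
                                            repeats = 1, seed = 1) {
  pv <- ba <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    series <- lapply(seq_len(2 * n_per_group), function(i)
      classification_series(duration_s, effect_size = 0,
                            seed = seed + d * 1000L + i))
    x <- extract_features(series)
    y <- factor(rep(c("ctl", "kd"), each = n_per_group))
    r <- permutation_pvalue(x, y, n_shuffles = n_shuffles,
                            repeats = repeats, folds = 5, seed = seed + d)
    pv[d] <- r$p_value
    ba[d] <- r$balanced_accuracy
  }
  list(fpr = mean(pv < 0.05), p_values = pv, balanced_accuracies = ba)
}

#' Classification of a strongly separated synthetic contrast
#'
#' Generates one dataset with a large behavioural effect (the treated
#' group's immobility dwell times scaled by `exp(3)` and locomotion by
#' `exp(-3)`, long sessions) and runs the full permutation-tested
#' classification.
#'
#' @param n_per_group Animals per group (default 20).
#' @param duration_s Session length (default 300 s).
#' @param effect_size Dwell-time log-fold effect (default 3).
#' @param n_shuffles Permutation shuffles (default 200).
#' @param seed Base seed.
#' @return The `classification_result`.
#' @export
separable_classification <- function(n_per_group = 20, duration_s = 300,
                                     effect_size = 3, n_shuffles = 200,
                                     seed = 1) {
  labels <- rep(c("ctl", "kd"), each = n_per_group)
  series <- lapply(seq_len(2 * n_per_group), function(i)
    classification_series(duration_s,
                          effect_size = if (labels[i] == "kd")
                            effect_size else 0,
                          seed = seed + i))
  x <- extract_features(series)
  permutation_pvalue(x, factor(labels), n_shuffles = n_shuffles,
                     repeats = 5, folds = 5, seed = seed)
}
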