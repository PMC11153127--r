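#' Reduced time-series feature catalogue
#'
#' Computes a fixed, versioned catalogue of 41 summary features of a
#' univariate series: moments, quantiles, autocorrelations at lags
#' 1/2/5/10/20, crossing rates, spectral band powers and entropy,
#' permutation entropy, split-half stationarity measures, run lengths,
#' outlier fractions, difference statistics, linear trend and Hjorth
#' parameters. Degenerate inputs follow fixed conventions: for a constant
#' series the variance is 0 and autocorrelations, entropies, crossing rates
#' and outlier fractions are all defined as 0.
#'
#' @param x Numeric series, length at least 64.
#' @return Named numeric vector of length 41 with the catalogue id in
#'   `attr(, "catalogue")`.
#' @export
ts_features <- function(x) {
  n <- length(x)
  if (n < 64L) stop("series too short: need at least 64 samples, got ", n)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("series contains non-finite values")

  m <- mean(x)
  s <- stats::sd(x)
  const <- s == 0
  z <- if (const) rep(0, n) else (x - m) / s

  qs <- stats::quantile(x, c(.01, .05, .25, .5, .75, .95, .99), names = FALSE)

  acf_lags <- c(1L, 2L, 5L, 10L, 20L)
  if (const) {
    ac <- rep(0, length(acf_lags))
    ac_decay <- 0
  } else {
    a <- stats::acf(x, lag.max = 20L, plot = FALSE, demean = TRUE)$acf[-1L]
    ac <- a[acf_lags]
    below <- which(a < exp(-1))
    ac_decay <- (if (length(below)) below[1L] else 21L) / 20
  }

  cross_rate <- function(v) {
    sgn <- sign(v)
    sgn <- sgn[sgn != 0]
    if (length(sgn) < 2L) return(0)
    mean(diff(sgn) != 0)
  }
  mean_cross <- cross_rate(x - m)
  median_cross <- cross_rate(x - stats::median(x))

  if (const) {
    bands <- rep(0, 4); sc <- 0; se <- 0
  } else {
    xd <- x - m
    p <- Mod(stats::fft(xd))^2
    half <- p[2:(floor(n / 2) + 1L)]
    freq <- seq_along(half) / n          # cycles per sample, (0, 0.5]
    tot <- sum(half)
    bands <- vapply(list(c(0, .1), c(.1, .2), c(.2, .35), c(.35, .5)),
                    function(b) sum(half[freq > b[1] & freq <= b[2]]) / tot, 0)
    sc <- sum(freq * half) / tot
    pn <- half / tot
    pn <- pn[pn > 0]
    se <- -sum(pn * log(pn)) / log(length(half))
  }

  # permutation entropy, order 3, normalized by log(3!)
  if (const) {
    pe <- 0
  } else {
    a1 <- x[1:(n - 2L)]; a2 <- x[2:(n - 1L)]; a3 <- x[3:n]
    # the ranks of the first two elements identify the ordinal pattern
    pat <- paste((a1 > a2) + (a1 > a3), (a2 > a1) + (a2 > a3), sep = ".")
    tab <- table(pat)
    pp <- tab / sum(tab)
    pe <- -sum(pp * log(pp)) / log(6)
  }

  h1 <- x[1:(n %/% 2)]; h2 <- x[(n %/% 2 + 1L):n]
  split_mean_shift <- if (const) 0 else abs(mean(h1) - mean(h2)) / s
  split_sd_ratio <- if (const) 0 else
    abs(stats::sd(h1) - stats::sd(h2)) / s

  longest_run <- function(flag) {
    r <- rle(flag)
    suppressWarnings(max(r$lengths[r$values], 0))
  }
  # a run of k zero first-differences spans k + 1 equal samples
  flat_run_frac <- (longest_run(diff(x) == 0) + 1) / n
  above_mean_run_frac <- longest_run(x > m) / n

  frac_z2 <- mean(abs(z) > 2)
  frac_z3 <- mean(abs(z) > 3)

  mad_over_sd <- if (const) 0 else stats::mad(x) / s
  d1 <- diff(x)
  mean_abs_diff <- mean(abs(d1))
  diff_acf1 <- if (stats::sd(d1) == 0) 0 else
    stats::acf(d1, lag.max = 1L, plot = FALSE)$acf[2L]

  tt <- seq_len(n) - (n + 1) / 2
  slope <- sum(tt * (x - m)) / sum(tt^2)
  trend_slope <- if (const) 0 else slope * n / s
  fitted <- m + slope * tt
  trend_r2 <- if (const) 0 else sum((fitted - m)^2) / sum((x - m)^2)

  sd1 <- stats::sd(d1)
  d2 <- diff(d1)
  hjorth_mobility <- if (const) 0 else sd1 / s
  hjorth_complexity <- if (sd1 == 0) 0 else
    (stats::sd(d2) / sd1) / max(hjorth_mobility, .Machine$double.eps)

  out <- c(
    mean = m, sd = s,
    skewness = if (const) 0 else e1071::skewness(x),
    kurtosis = if (const) 0 else e1071::kurtosis(x),
    q01 = qs[1], q05 = qs[2], q25 = qs[3], q50 = qs[4], q75 = qs[5],
    q95 = qs[6], q99 = qs[7],
    iqr = qs[5] - qs[3], range = diff(range(x)),
    acf1 = ac[1], acf2 = ac[2], acf5 = ac[3], acf10 = ac[4], acf20 = ac[5],
    acf_decay = ac_decay,
    mean_cross_rate = mean_cross, median_cross_rate = median_cross,
    band_low = bands[1], band_midlow = bands[2], band_midhigh = bands[3],
    band_high = bands[4], spec_centroid = sc, spec_entropy = se,
    perm_entropy = pe,
    split_mean_shift = split_mean_shift, split_sd_ratio = split_sd_ratio,
    flat_run_frac = flat_run_frac, above_mean_run_frac = above_mean_run_frac,
    frac_z2 = frac_z2, frac_z3 = frac_z3,
    mad_over_sd = mad_over_sd, mean_abs_diff = mean_abs_diff,
    diff_acf1 = diff_acf1,
    trend_slope = trend_slope, trend_r2 = trend_r2,
    hjorth_mobility = hjorth_mobility, hjorth_complexity = hjorth_complexity
  )
  attr(out, "catalogue") <- TS_CATALOGUE_VERSION
  out
}

#' @rdname ts_features
#' @export
TS_CATALOGUE_VERSION <- "opiometrics-catalogue-v1"

#' Extract a feature matrix from a list of series
#'
#' @param series A list of numeric vectors (one per animal) or a matrix
#'   with one series per row.
#' @return Numeric matrix, one row per series, 41 named feature columns;
#'   catalogue id in `attr(, "catalogue")`.
#' @export
extract_features <- function(series) {
  if (is.matrix(series))
    series <- lapply(seq_len(nrow(series)), function(i) series[i, ])
  out <- t(vapply(series, ts_features, numeric(41L)))
  attr(out, "catalogue") <- TS_CATALOGUE_VERSION
  out
}

# stratified fold assignment, invariant to the row order of (x, labels):
# rows are put in a canonical lexicographic order within each class before
# the seeded deal, so jointly permuting rows does not change the partition
stratified_folds <- function(rank_canon, labels, folds, seed) {
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[order(rank_canon[idx])]
      assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assignment
}

# decision values of a fitted linear SVM, computed directly from the
# support vectors: f(x) = x w' - rho with w = coefs' SV (exact for the
# linear kernel; avoids predict.svm overhead in tight loops)
linear_svm_predict <- function(fit, newdata) {
  w <- crossprod(fit$coefs, fit$SV)
  dec <- as.numeric(newdata %*% t(w)) - fit$rho
  # libsvm orders decision values by fit$labels: positive -> labels[1]
  lv <- fit$levels[fit$labels]
  factor(ifelse(dec > 0, lv[1L], lv[2L]), levels = fit$levels)
}

# standardize by training statistics; drop constant columns; impute
# non-finite entries with the training median
standardize_pair <- function(train, test) {
  if (any(!is.finite(train)) || any(!is.finite(test))) {
    med <- apply(train, 2L, function(v) stats::median(v[is.finite(v)]))
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(train))) {
      train[!is.finite(train[, j]), j] <- med[j]
      test[!is.finite(test[, j]), j] <- med[j]
    }
  }
  n <- nrow(train)
  mu <- colMeans(train)
  sg <- sqrt(pmax(colSums(train^2) / n - mu^2, 0) * n / (n - 1))
  keep <- sg > 0
  list(train = t((t(train[, keep, drop = FALSE]) - mu[keep]) / sg[keep]),
       test = t((t(test[, keep, drop = FALSE]) - mu[keep]) / sg[keep]))
}

#' Balanced accuracy
#'
#' `(sensitivity + specificity) / 2`: the classification metric used
#' throughout, robust to class imbalance.
#'
#' @param sensitivity,specificity True-positive and true-negative rates.
#' @return Numeric balanced accuracy.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Cross-validated balanced accuracy of a linear SVM
#'
#' Repeated stratified k-fold cross-validation of a linear support-vector
#' classifier (fixed cost, no tuning). Features are standardized with
#' training-fold statistics only; constant columns are dropped and
#' non-finite entries imputed with the training median. Per fold,
#' sensitivity and specificity are computed and the balanced accuracy is
#' their mean; the reported figure is the mean over all folds and repeats.
#'
#' @param features Numeric matrix, rows = subjects, columns = features.
#' @param labels Two-level factor (or coercible) of group labels.
#' @param repeats Number of CV repeats (default 5).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param cost SVM cost parameter (default 1).
#' @param rank_canon Precomputed canonical row ranking (internal; used by
#'   [permutation_pvalue()] to avoid recomputation across shuffles).
#' @return An object of class `classification_result`: mean
#'   `balanced_accuracy`, per-fold table `fold_results`, and the settings.
#' @export
cv_balanced_accuracy <- function(features, labels, repeats = 5L, folds = 5L,
                                 seed = 1L, cost = 1, rank_canon = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  counts <- table(labels)
  if (any(counts < folds))
    stop("class '", names(counts)[which.min(counts)], "' has fewer members (",
         min(counts), ") than folds (", folds, "); use fewer folds")
  pos <- levels(labels)[2L]
  neg <- levels(labels)[1L]

  # canonical row order (for order-invariant fold assignment), computed once
  if (is.null(rank_canon))
    rank_canon <- order(do.call(order, as.data.frame(features)))

  nres <- repeats * folds
  res_rep <- integer(nres); res_fold <- integer(nres)
  res_sens <- numeric(nres); res_spec <- numeric(nres)
  r <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(rank_canon, labels, folds,
                                seed = seed * 1000L + rep_i)
    for (k in seq_len(folds)) {
      te <- fold_of == k
      std <- standardize_pair(features[!te, , drop = FALSE],
                              features[te, , drop = FALSE])
      fit <- e1071::svm(std$train, labels[!te], kernel = "linear",
                        cost = cost, scale = FALSE, fitted = FALSE)
      pred <- linear_svm_predict(fit, std$test)
      truth <- labels[te]
      r <- r + 1L
      res_rep[r] <- rep_i; res_fold[r] <- k
      res_sens[r] <- mean(pred[truth == pos] == pos)
      res_spec[r] <- mean(pred[truth == neg] == neg)
    }
  }
  fold_results <- data.frame(rep = res_rep, fold = res_fold,
                             sensitivity = res_sens, specificity = res_spec,
                             ba = balanced_accuracy(res_sens, res_spec))
  structure(list(
    balanced_accuracy = mean(fold_results$ba),
    fold_results = fold_results,
    repeats = repeats, folds = folds, cost = cost, seed = seed,
    catalogue = TS_CATALOGUE_VERSION,
    null = NULL, p_value = NULL, n_shuffles = 0L
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> mean balanced accuracy ",
      round(x$balanced_accuracy, 3), " (", x$repeats, "x", x$folds,
      " CV)", sep = "")
  if (!is.null(x$p_value))
    cat(", permutation p = ", signif(x$p_value, 3),
        " (", x$n_shuffles, " shuffles)", sep = "")
  cat("\n")
  invisible(x)
}

#' Permutation significance of the classification
#'
#' Reruns the full cross-validation on `n_shuffles` label-shuffled copies
#' of the data and compares the observed balanced accuracy with the null
#' distribution. The p-value uses the add-one estimator
#' `p = (1 + #[null >= observed]) / (n_shuffles + 1)`, which cannot reach 0.
#'
#' @inheritParams cv_balanced_accuracy
#' @param n_shuffles Number of label shuffles (default 1000).
#' @return A `classification_result` with `null` (the null balanced
#'   accuracies) and `p_value` filled in.
#' @export
permutation_pvalue <- function(features, labels, n_shuffles = 1000L,
                               repeats = 5L, folds = 5L, seed = 1L,
                               cost = 1) {
  if (n_shuffles < 1L) stop("n_shuffles must be at least 1")
  labels <- factor(labels)
  features <- as.matrix(features)
  rank_canon <- order(do.call(order, as.data.frame(features)))
  obs <- cv_balanced_accuracy(features, labels, repeats, folds, seed, cost,
                              rank_canon = rank_canon)
  null <- vapply(seq_len(n_shuffles), function(s) {
    shuffled <- withr::with_seed(seed * 100000L + s, sample(labels))
    cv_balanced_accuracy(features, shuffled, repeats, folds,
                         seed = seed + s, cost = cost,
                         rank_canon = rank_canon)$balanced_accuracy
  }, 0)
  obs$null <- null
  obs$n_shuffles <- n_shuffles
  obs$p_value <- (1 + sum(null >= obs$balanced_accuracy)) / (n_shuffles + 1)
  obs
}
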