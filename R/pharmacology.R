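#' Four-parameter logistic (log-dose) response
#'
#' `response = bottom + (top - bottom) / (1 + 10^((log10(ic50) -
#' log10(dose)) * hill))`, the Prism-style variable-slope sigmoid with a
#' signed Hill coefficient: for a response that decreases with dose the
#' Hill coefficient is negative and the curve runs from `top` at low doses
#' to `bottom` at high doses. `dose = 0` is handled by the limit (`top`
#' for `hill < 0`, `bottom` for `hill > 0`).
#'
#' @param dose Dose(s), non-negative, same units as `ic50`.
#' @param top,bottom Upper and lower response asymptotes.
#' @param ic50 Half-maximal dose, must be positive.
#' @param hill Signed Hill slope.
#' @return Numeric response vector.
#' @export
logistic4 <- function(dose, top, bottom, ic50, hill) {
  if (ic50 <= 0) stop("ic50 must be positive")
  if (any(dose < 0)) stop("doses must be non-negative")
  out <- numeric(length(dose))
  z <- dose == 0
  out[z] <- if (hill < 0) top else if (hill > 0) bottom else
    bottom + (top - bottom) / 2
  d <- dose[!z]
  out[!z] <- bottom + (top - bottom) /
    (1 + 10^((log10(ic50) - log10(d)) * hill))
  out
}

#' Fit the four-parameter logistic dose-response curve
#'
#' Nonlinear least squares on log10 dose (via [minpack.lm::nlsLM]),
#' initialized from the data (top = mean response at the lowest dose,
#' bottom = mean at the highest, IC50 = geometric mid-dose, hill = -1)
#' with `n_starts` jittered restarts; the lowest-SS converged fit wins.
#' Zero-dose rows (e.g. saline baseline) are excluded from the fit by
#' default because log-dose is undefined there.
#'
#' @param table data.frame with numeric columns `dose` and `response`
#'   (one row per subject and dose).
#' @param n_starts Number of jittered starts (default 5).
#' @param include_zero_dose If TRUE, zero doses are mapped to one decade
#'   below the smallest tested dose instead of being dropped.
#' @param seed Seed for the start jitter.
#' @return An object of class `dose_response_fit`: `estimates` (top,
#'   bottom, ic50, hill), `se`, `rss`, `converged`, `n_obs`, and the
#'   fitted `model`. Non-convergence from all starts, or a degenerate
#'   (constant-response) input, yields `converged = FALSE` with a
#'   diagnostic message rather than a spurious fit.
#' @export
fit_logistic4 <- function(table, n_starts = 5L, include_zero_dose = FALSE,
                          seed = 1L) {
  stopifnot(all(c("dose", "response") %in% names(table)))
  tab <- table[is.finite(table$dose) & is.finite(table$response), ]
  if (include_zero_dose && any(tab$dose == 0)) {
    dmin <- min(tab$dose[tab$dose > 0])
    tab$dose[tab$dose == 0] <- dmin / 10
  } else {
    tab <- tab[tab$dose > 0, ]
  }
  if (length(unique(tab$dose)) < 4L)
    stop("need at least 4 distinct positive doses")

  fail <- function(msg) structure(
    list(estimates = c(top = NA_real_, bottom = NA_real_,
                       ic50 = NA_real_, hill = NA_real_),
         se = NULL, rss = NA_real_, converged = FALSE,
         message = msg, n_obs = nrow(tab), model = NULL),
    class = "dose_response_fit")

  by_dose <- tapply(tab$response, tab$dose, mean)
  doses <- as.numeric(names(by_dose))
  if (stats::sd(tab$response) == 0 ||
      max(by_dose) - min(by_dose) < 1e-12 * max(abs(by_dose), 1))
    return(fail("degenerate input: response does not vary with dose"))

  top0 <- unname(by_dose[which.min(doses)])
  bottom0 <- unname(by_dose[which.max(doses)])
  lic0 <- mean(log10(range(doses)))
  hill0 <- -1
  ld <- log10(tab$dose)

  starts <- withr::with_seed(seed, lapply(seq_len(n_starts), function(i) {
    j <- if (i == 1L) c(0, 0, 0, 0) else
      c(stats::rnorm(2, 0, 0.1 * max(abs(top0 - bottom0), 1e-6)),
        stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.3))
    list(top = top0 + j[1], bottom = bottom0 + j[2],
         lic50 = lic0 + j[3], hill = hill0 + j[4])
  }))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + 10^((lic50 - ld) * hill)),
        data = data.frame(response = tab$response, ld = ld),
        start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(fail("no start converged"))

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 4), names(cf)))
  ic50 <- 10^cf[["lic50"]]
  se_ic50 <- if (is.finite(se[["lic50"]]))
    ic50 * log(10) * se[["lic50"]] else NA_real_
  structure(list(
    estimates = c(top = cf[["top"]], bottom = cf[["bottom"]],
                  ic50 = ic50, hill = cf[["hill"]]),
    se = c(top = se[["top"]], bottom = se[["bottom"]],
           ic50 = se_ic50, hill = se[["hill"]]),
    rss = best$rss, converged = TRUE, message = "ok",
    n_obs = nrow(tab), model = best$fit
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<dose_response_fit> FAILED: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  e <- x$estimates
  cat("<dose_response_fit> IC50 = ", signif(e[["ic50"]], 4),
      ", hill = ", signif(e[["hill"]], 3),
      ", top = ", signif(e[["top"]], 3),
      ", bottom = ", signif(e[["bottom"]], 3),
      " (RSS ", signif(x$rss, 3), ", n = ", x$n_obs, ")\n", sep = "")
  invisible(x)
}

#' Occlusion dose-response summary
#'
#' Normalizes each subject's per-minute response rates to its own saline
#' (zero-dose) baseline and summarises per dose as mean and SEM of the
#' fraction of baseline.
#'
#' @param rates data.frame with columns `subject`, `dose` and `rate`
#'   (responses per minute); rows with `dose == 0` are the saline baseline.
#' @return data.frame with `dose`, `mean_rate`, `sem`, `n` (normalized
#'   rates; 1 = baseline).
#' @export
occlusion_curve <- function(rates) {
  stopifnot(all(c("subject", "dose", "rate") %in% names(rates)))
  base <- tapply(rates$rate[rates$dose == 0], rates$subject[rates$dose == 0],
                 mean)
  if (!length(base)) stop("missing baseline: no zero-dose (saline) rows")
  subj <- as.character(rates$subject)
  if (any(!subj %in% names(base)))
    stop("missing baseline for subject(s): ",
         paste(unique(subj[!subj %in% names(base)]), collapse = ", "))
  norm <- rates$rate / as.numeric(base[subj])
  agg <- split(norm, rates$dose)
  data.frame(
    dose = as.numeric(names(agg)),
    mean_rate = vapply(agg, mean, 0),
    sem = vapply(agg, function(v)
      stats::sd(v) / sqrt(length(v)), 0),
    n = lengths(agg),
    row.names = NULL
  )
}
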