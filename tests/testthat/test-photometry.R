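test_that("isosbestic regression is fit on baseline and applied globally", {
  t <- seq(0, 600, by = 0.05)
  f405 <- 100 + 5 * exp(-t / 600) + sin(t / 7)
  # identical channels: identity regression
  rec <- fit_isosbestic(photometry_recording(t, f405, f405, c(0, 300)))
  cf <- attr(rec$fitted405, "coef")
  expect_equal(unname(cf), c(0, 1), tolerance = 1e-9)
  expect_equal(as.numeric(rec$fitted405), f405, tolerance = 1e-9)
  # exact affine relation recovered to numerical precision
  rec2 <- fit_isosbestic(photometry_recording(t, 2 * f405 + 3, f405,
                                              c(0, 300)))
  expect_equal(unname(attr(rec2$fitted405, "coef")), c(3, 2),
               tolerance = 1e-10)
  # constant control on baseline is singular
  f_const <- rep(100, length(t))
  expect_error(fit_isosbestic(photometry_recording(t, f405, f_const,
                                                   c(0, 300))), "singular")
})

test_that("dF/F follows the printed formula elementwise", {
  t <- seq(0, 100, by = 0.05)
  f405 <- 100 + sin(t / 5)
  rec <- photometry_recording(t, f405, f405, c(0, 50))
  rec <- compute_dff(fit_isosbestic(rec))
  expect_equal(as.numeric(rec$dff), rep(0, length(t)), tolerance = 1e-10)
  rec2 <- photometry_recording(t, 1.1 * f405, f405, c(0, 50))
  rec2 <- compute_dff(fit_isosbestic(rec2))
  # fit absorbs the 1.1 into the scaling; construct the direct case instead
  rec3 <- photometry_recording(t, 1.1 * f405, f405, c(0, 50))
  rec3$fitted405 <- f405
  rec3 <- compute_dff(rec3)
  expect_equal(as.numeric(rec3$dff), rep(0.1, length(t)), tolerance = 1e-12)
  # non-positive fitted control is masked and counted
  rec4 <- photometry_recording(t, f405, f405, c(0, 50))
  rec4$fitted405 <- c(-1, f405[-1])
  rec4 <- compute_dff(rec4)
  expect_true(is.na(rec4$dff[1]))
  expect_equal(attr(rec4$dff, "n_masked"), 1L)
})

test_that("binning averages 10-s windows and flags partial bins", {
  fps <- 20
  dff <- rep(0.3, 20 * fps)
  b <- bin_dff(dff, fps = fps)
  expect_equal(b$mean, rep(0.3, 2))
  expect_equal(formals(bin_dff)$bin_s, 10)
  # linear ramp over one bin has mean ~ 0.5
  t <- seq(0, 10 - 1 / fps, by = 1 / fps)
  b2 <- bin_dff(t / 10, t = t, bin_s = 10)
  expect_equal(b2$mean, 0.4975)   # mean of t/10 over the sampled grid
  # trailing partial bin flagged
  b3 <- bin_dff(rep(1, 25 * fps), fps = fps)
  expect_equal(b3$partial, c(FALSE, FALSE, TRUE))
})

test_that("peak prominence matches a brute-force oracle", {
  brute <- function(x) {
    n <- length(x)
    pk <- which(diff(sign(diff(x))) < 0) + 1L
    pk <- pk[x[pk] > x[pk - 1L]]   # first sample of any plateau
    vapply(pk, function(i) {
      higher_l <- which(x[1:(i - 1L)] > x[i])
      higher_r <- which(x[(i + 1L):n] > x[i]) + i
      lh <- if (length(higher_l)) max(higher_l) else 1L
      rh <- if (length(higher_r)) min(higher_r) else n
      x[i] - max(min(x[lh:i]), min(x[i:rh]))
    }, 0)
  }
  set.seed(21)
  for (rep_i in 1:5) {
    x <- cumsum(rnorm(300))
    got <- peak_prominences(x)
    expect_equal(got$prominence, brute(x), tolerance = 1e-12)
  }
})

test_that("transient detection applies the 2-SD prominence rule", {
  expect_equal(formals(detect_transients)$k, 2)
  rate <- 20
  t <- seq(0, 600 - 1 / rate, by = 1 / rate)
  # flat zero signal: no transients
  flat <- detect_transients(rep(0, length(t)), t = t,
                            baseline_window = c(0, 300))
  expect_equal(nrow(flat), 0L)
  # quiet baseline: a slow monotone drift (nonzero SD, no local maxima),
  # then one kernel of 5 sigma prominence
  a <- 0.01
  base <- ifelse(t <= 300, a * t / 300, a)
  sd0 <- sd(base[t <= 300])
  kern <- exp(-(0:39) / 8) * (1 - exp(-(0:39) / 1.5))
  kern <- 5 * sd0 * kern / max(kern)
  sig <- base
  i0 <- 400 * rate
  sig[i0:(i0 + 39)] <- sig[i0:(i0 + 39)] + kern
  tr <- detect_transients(sig, t = t, baseline_window = c(0, 300))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$time, t[i0 + which.max(kern) - 1L], tolerance = 1e-9)
  expect_equal(tr$prominence, 5 * sd0, tolerance = 1e-6)
  # two peaks closer than the minimum separation: only the taller reported
  sig2 <- base
  sig2[i0] <- a + 10 * sd0
  sig2[i0 + 5] <- a + 8 * sd0
  tr2 <- detect_transients(sig2, t = t, baseline_window = c(0, 300))
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$height, a + 10 * sd0)
})

test_that("AUC is the trapezoidal integral over the window", {
  rate <- 20
  t <- seq(0, 60, by = 1 / rate)
  expect_equal(compute_auc(rep(0, length(t)), t, c(10, 20)), 0)
  expect_equal(compute_auc(rep(1, length(t)), t, c(10, 20)), 10)
  # triangle of height 1 on base 10 s
  tri <- pmax(0, 1 - abs(t - 30) / 5)
  expect_equal(compute_auc(tri, t, c(20, 40)), 5, tolerance = 1 / rate)
  # linearity is exact
  expect_equal(compute_auc(3.7 * tri, t, c(20, 40)),
               3.7 * compute_auc(tri, t, c(20, 40)))
  expect_error(compute_auc(tri, t, c(100, 110)), "empty")
})

test_that("trapezoidal AUC converges at O(dt^2) on smooth signals", {
  f <- function(t) t^3 - 2 * t^2 + t          # exact integral over [0,2]: 2/3
  exact <- 2 / 3
  err <- vapply(c(0.02, 0.01), function(dt) {
    t <- seq(0, 2, by = dt)
    abs(compute_auc(f(t), t, c(0, 2)) - exact)
  }, 0)
  expect_lt(err[2], err[1] / 3.5)   # halving dt cuts error ~4x
})

test_that("AUC normalization reports both orientations", {
  r <- normalize_auc(1, 1)
  expect_equal(r$apo_over_fent, 1)
  r2 <- normalize_auc(auc_fentanyl = 1, auc_apomorphine = 2)
  expect_equal(r2$apo_over_fent, 2)
  expect_equal(r2$fent_over_apo, 0.5)
  expect_error(normalize_auc(0, 2), "zero")
})

test_that("peri-event averaging aligns trials and drops clipped events", {
  rate <- 20
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  kern <- exp(-(0:19) / 5)
  dff <- rep(0, length(t))
  events <- c(30, 60, 90)
  for (e in events) {
    i <- e * rate + 1
    dff[i:(i + 19)] <- dff[i:(i + 19)] + kern
  }
  pe <- peri_event_average(dff, t, events, window = c(-2, 4))
  expect_equal(pe$n_events, 3L)
  expect_equal(dim(pe$trials), c(3L, 121L))
  # identical trials: mean equals any single trial
  expect_equal(pe$mean, pe$trials[1, ])
  # average peaks at offset 0 (within one sample)
  expect_lte(abs(pe$offset_s[which.max(pe$mean)]), 1 / rate + 1e-9)
  # single event: mean is that trial's segment
  pe1 <- peri_event_average(dff, t, events[1], window = c(-2, 4))
  expect_equal(pe1$mean, as.numeric(pe1$trials[1, ]))
  # events clipped by the edges are dropped and counted
  pe2 <- peri_event_average(dff, t, c(0.5, 60), window = c(-2, 4))
  expect_equal(pe2$n_events, 1L)
  expect_equal(pe2$n_dropped, 1L)
  expect_error(peri_event_average(dff, t, 0.5, window = c(-2, 4)),
               "no usable events")
})

test_that("isosbestic correction removes a shared motion artifact", {
  ses <- gen_photometry_session(photometry_scenario(transient_rate = 0,
                                                    seed = 31))
  rec <- compute_dff(fit_isosbestic(ses$recording))
  rms <- function(v) sqrt(mean(v^2))
  uncorrected <- (rec$f470 - mean(rec$f470)) / mean(rec$f470)
  expect_lt(rms(rec$dff) / rms(uncorrected), 0.10)
})
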