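test_that("generators are deterministic given a seed", {
  a <- gen_pose_session(pose_scenario(duration_s = 20, seed = 1))
  b <- gen_pose_session(pose_scenario(duration_s = 20, seed = 1))
  expect_identical(a$track, b$track)
  expect_identical(a$truth, b$truth)
  c <- gen_pose_session(pose_scenario(duration_s = 20, seed = 2))
  expect_false(identical(a$track$x, c$track$x))

  p1 <- gen_photometry_session(photometry_scenario(duration_s = 400,
                                                   seed = 3))
  p2 <- gen_photometry_session(photometry_scenario(duration_s = 400,
                                                   seed = 3))
  expect_identical(p1$recording$f470, p2$recording$f470)
  expect_identical(p1$truth, p2$truth)

  d1 <- gen_dose_response(doses = c(10, 100), n_subjects = 3, seed = 7)
  d2 <- gen_dose_response(doses = c(10, 100), n_subjects = 3, seed = 7)
  expect_identical(d1, d2)

  o1 <- gen_preference_session(c(target = 30, other = 20, corridor = 10),
                               seed = 5)
  o2 <- gen_preference_session(c(target = 30, other = 20, corridor = 10),
                               seed = 5)
  expect_identical(o1, o2)
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_pose_session(pose_scenario(duration_s = 5, seed = 1)))
  invisible(gen_photometry_session(photometry_scenario(duration_s = 60,
                                                       seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("an immobile-only program yields one session-long bout, no jumps", {
  sc <- pose_scenario(duration_s = 60, jump_rate = 0,
                      state_program = list(immobile = list(mean_s = 10,
                                                           shape = 2)),
                      seed = 4)
  ses <- gen_pose_session(sc)
  expect_equal(nrow(ses$truth$jumps), 0L)
  expect_equal(nrow(ses$truth$immobility), 1L)
  expect_equal(ses$truth$immobility$duration_s, 60)
})

test_that("jump counts follow the programmed Poisson rate", {
  # rate 3/min for 600 s: count within the Poisson 99% interval of 30,
  # slightly widened for the 2-s spacing thinning
  sc <- pose_scenario(duration_s = 600, jump_rate = 3, seed = 6)
  ses <- gen_pose_session(sc)
  expect_gte(nrow(ses$truth$jumps), qpois(0.005, 30) - 2)
  expect_lte(nrow(ses$truth$jumps), qpois(0.995, 30))
})

test_that("invalid scenarios are rejected", {
  expect_error(pose_scenario(duration_s = 0), "invalid scenario")
  expect_error(pose_scenario(fps = -1), "invalid scenario")
  expect_error(pose_scenario(dropout_likelihood = 1.2), "invalid scenario")
  expect_error(photometry_scenario(transient_kernel = c(rise = -0.1,
                                                        decay = 0.5,
                                                        amplitude = 0.05)),
               "invalid scenario")
  expect_error(photometry_scenario(rate_hz = 0), "invalid scenario")
})

test_that("every generated jump drops the tracking confidence below 0.5", {
  ses <- gen_pose_session(pose_scenario(duration_s = 300, jump_rate = 3,
                                        seed = 9))
  conf <- 1 - jump_likelihood_series(ses$track)
  expect_gt(nrow(ses$truth$jumps), 0)
  for (i in seq_len(nrow(ses$truth$jumps)))
    expect_lt(min(conf[ses$truth$jumps$onset[i]:ses$truth$jumps$offset[i]]),
              0.5)
  expect_true(all(ses$track$likelihood >= 0 & ses$track$likelihood <= 1))
})

test_that("photometry truth counts follow the transient rate", {
  sc <- photometry_scenario(duration_s = 1200, transient_rate = 2, seed = 10)
  ses <- gen_photometry_session(sc)
  expect_gte(nrow(ses$truth), qpois(0.005, 40))
  expect_lte(nrow(ses$truth), qpois(0.995, 40))
})

test_that("a noiseless null photometry scenario corrects to zero dF/F", {
  sc <- photometry_scenario(noise_sd = 0, transient_rate = 0, seed = 2)
  ses <- gen_photometry_session(sc)
  rec <- compute_dff(fit_isosbestic(ses$recording))
  expect_lt(max(abs(rec$dff)), 1e-10)
})

test_that("dose-response tables follow the logistic with truncation", {
  # CV = 0: responses exactly on the curve
  tab <- gen_dose_response(doses = c(50, 100, 200), n_subjects = 4,
                           top = 1, bottom = 0, ic50 = 100, hill = -2,
                           cv = 0, seed = 1)
  expect_equal(tab$response,
               logistic4(tab$dose, 1, 0, 100, -2))
  # half-maximal point at dose = ic50
  expect_equal(tab$response[tab$dose == 100], rep(0.5, 4))
  # 9 subjects x 7 doses = 63 rows
  tab2 <- gen_dose_response(doses = c(0, 60, 120, 150, 180, 210, 300),
                            n_subjects = 9, seed = 2)
  expect_equal(nrow(tab2), 63L)
  expect_true(all(tab2$response >= 0))
  expect_error(gen_dose_response(doses = numeric(0)), "empty")
  expect_error(gen_dose_response(doses = c(-1, 10)), "non-negative")
})

test_that("occupancy tracks honour the requested dwell times", {
  occ <- gen_preference_session(c(target = 600, other = 600, corridor = 0),
                                fps = 40)
  expect_equal(place_preference_score(occ$compartment, "target"), 0.5)
  occ2 <- gen_preference_session(c(target = 300, other = 100,
                                   corridor = 50), fps = 40)
  expect_equal(place_preference_score(occ2$compartment, "target"), 0.75)
  # frame counts: 20 min at 40 fps = 48,000 frames
  occ3 <- gen_preference_session(c(target = 500, other = 500,
                                   corridor = 200), fps = 40)
  expect_equal(nrow(occ3), 48000L)
  # dwell times match to within one frame
  tt <- table(occ2$compartment)
  expect_equal(unname(tt[["target"]] / 40), 300, tolerance = 1 / 40)
  expect_error(gen_preference_session(c(0, 0, 0)), "total time")
  expect_error(gen_preference_session(c(-1, 10, 0)), "non-negative")
})

test_that("the x coordinate of the occupancy track matches its compartment", {
  occ <- gen_preference_session(c(target = 40, other = 30, corridor = 20),
                                fps = 40, seed = 3)
  geom <- attr(occ, "geometry")
  for (cmp in names(geom$x_range)) {
    xr <- geom$x_range[[cmp]]
    xs <- occ$x[occ$compartment == cmp]
    expect_true(all(xs >= xr[1] - 1e-9 & xs <= xr[2] + 1e-9))
  }
})
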