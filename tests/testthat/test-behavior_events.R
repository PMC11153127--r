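make_conf_track <- function(n, low_frames = integer(), fps = 40) {
  trk <- static_track(n, fps = fps)
  trk$likelihood[low_frames, ANIMAL_POINTS] <- 0.2
  trk
}

test_that("the jump rule combines low confidence with a speed peak", {
  n <- 200
  speed <- rep(0, n)
  # 4-frame low-confidence run with a 15 cm/s peak just outside it
  trk <- make_conf_track(n, 100:103)
  speed[105] <- 15
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 1L)
  # same run with only 5 cm/s in the window: not a jump
  speed[105] <- 5
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 0L)
  # speed peak outside the +-0.25 s window does not count
  speed <- rep(0, n); speed[130] <- 50
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 0L)
  # perfect confidence: no jumps regardless of speed
  trk2 <- make_conf_track(n)
  speed <- rep(20, n)
  expect_equal(nrow(detect_jumps(trk2, speed_series(speed))), 0L)
})

test_that("nearby low-confidence runs merge and short runs are discarded", {
  n <- 300
  speed <- rep(0, n); speed[c(95, 125)] <- 20
  # two runs 3 frames apart (< 0.125 s at 40 fps): merged into one jump
  trk <- make_conf_track(n, c(100:103, 107:110))
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 1L)
  # 10 frames apart: two distinct jumps
  trk <- make_conf_track(n, c(100:103, 114:117))
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 2L)
  # a single-frame run is below the minimum run length
  trk <- make_conf_track(n, 100)
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 0L)
})

test_that("jump thresholds default to 0.5 confidence and 10 cm/s", {
  expect_equal(formals(detect_jumps)$conf_thresh, 0.50)
  expect_equal(formals(detect_jumps)$speed_thresh, 10)
  # confidence exactly at threshold is not a dropout (strictly below)
  n <- 100
  trk <- static_track(n)
  trk$likelihood[40:45, ANIMAL_POINTS] <- 0.5
  speed <- rep(0, n); speed[39] <- 30
  expect_equal(nrow(detect_jumps(trk, speed_series(speed))), 0L)
})

test_that("immobility bouts need 2 s below threshold", {
  fps <- 40
  # 3 s of zero speed inside movement: one bout of 3 s
  speed <- c(rep(8, 2 * fps), rep(0, 3 * fps), rep(8, 2 * fps))
  imm <- detect_immobility(speed, fps = fps)
  expect_equal(nrow(imm), 1L)
  expect_equal(imm$duration_s, 3)
  # 1.5 s still: below the 2 s minimum
  speed <- c(rep(8, 2 * fps), rep(0, 1.5 * fps), rep(8, 2 * fps))
  expect_equal(nrow(detect_immobility(speed, fps = fps)), 0L)
})

test_that("alternating 2.5 s still / 2.5 s moving yields 12 bouts, 30 s", {
  fps <- 40
  speed <- rep(rep(c(0, 8), each = 2.5 * fps), 12)
  imm <- detect_immobility(speed, fps = fps)
  expect_equal(nrow(imm), 12L)
  expect_equal(attr(imm, "total_s"), 30)
})

test_that("single-frame glitches do not break a bout but jumps do", {
  fps <- 40
  speed <- rep(0, 10 * fps)
  speed[200] <- 30                          # 1-frame tracking glitch
  imm <- detect_immobility(speed, fps = fps)
  expect_equal(nrow(imm), 1L)
  # an excluded (detected-jump) window always splits the bout
  imm2 <- detect_immobility(speed, fps = fps,
                            exclude = data.frame(onset = 198, offset = 202))
  expect_equal(nrow(imm2), 2L)
})

test_that("raising thresholds is monotone for jumps and immobility", {
  ses <- gen_pose_session(pose_scenario(duration_s = 120, seed = 8))
  cal <- process_session(ses)
  kin <- compute_kinematics(cal)
  counts <- vapply(c(5, 10, 20, 40),
                   function(th) nrow(detect_jumps(cal, kin,
                                                  speed_thresh = th)), 0)
  expect_true(all(diff(counts) <= 0))
  v <- immobility_speed(cal)
  totals <- vapply(c(1, 2, 3, 5), function(mb)
    attr(detect_immobility(v, fps = 40, min_bout = mb), "total_s"), 0)
  expect_true(all(diff(totals) <= 0))
})

test_that("distance travelled integrates the centroid path in metres", {
  fps <- 40
  # stationary: 0 m
  expect_equal(distance_travelled(speed_series(rep(0, 200))), 0)
  # square path, side 0.5 m, traversed once: 2.0 m
  # (1 cm per frame at 40 fps = 40 cm/s for 200 frames)
  speed <- rep(40, 200)
  expect_equal(distance_travelled(speed_series(speed)), 2)
  # displacements inside jump windows are excluded
  jumps <- data.frame(onset = 1, offset = 100)
  expect_equal(distance_travelled(speed_series(speed), jumps), 1)
})

test_that("place preference is target time over both compartments", {
  expect_equal(place_preference_score(c(fent = 600, sal = 600, corridor = 0),
                                      "fent"), 0.5)
  expect_equal(place_preference_score(c(fent = 300, sal = 100, corridor = 50),
                                      "fent"), 0.75)
  # corridor time never enters the denominator
  expect_equal(place_preference_score(c(fent = 300, sal = 100,
                                        corridor = 1e6), "fent"), 0.75)
  # per-frame occupancy vectors work the same way
  occ <- rep(c("fent", "sal", "corridor"), c(30, 10, 60))
  expect_equal(place_preference_score(occ, "fent"), 0.75)
  # complementarity is exact
  expect_equal(place_preference_score(occ, "fent") +
                 place_preference_score(occ, "sal"), 1)
  expect_error(place_preference_score(c(fent = 0, sal = 0, corridor = 9),
                                      "fent"), "undefined")
})

test_that("quiescence segmentation recovers ground-truth immobility to one
          frame per bout", {
  for (s in 1:5) {
    ses <- gen_pose_session(pose_scenario(duration_s = 600, seed = 40 + s))
    cal <- process_session(ses)
    kin <- compute_kinematics(cal)
    jumps <- detect_jumps(cal, kin)
    seg <- detect_immobility(immobility_speed(cal), fps = cal$fps,
                             min_bout = 0, exclude = jumps)
    truth <- ses$truth$immobility
    truth <- truth[truth$duration_s >= 2, ]
    det_total <- 0
    for (i in seq_len(nrow(truth))) {
      ov <- seg[seg$onset <= truth$offset[i] & seg$offset >= truth$onset[i], ]
      det_total <- det_total + sum(ov$duration_s)
    }
    expect_lte(abs(det_total - sum(truth$duration_s)),
               nrow(truth) * 1 / cal$fps)
  }
})

test_that("event_table totals equal the sums over events", {
  ses <- gen_pose_session(pose_scenario(duration_s = 120, seed = 12))
  cal <- process_session(ses)
  kin <- compute_kinematics(cal)
  ev <- event_table(cal, kin)
  expect_equal(ev$totals$jump_count, nrow(ev$jumps))
  expect_equal(ev$totals$immobility_s, sum(ev$immobility$duration_s))
  expect_gte(ev$totals$distance_m, 0)
  # events are ordered and non-overlapping
  if (nrow(ev$immobility) > 1L)
    expect_true(all(diff(ev$immobility$onset) > 0) &&
                  all(ev$immobility$onset[-1] >
                        ev$immobility$offset[-nrow(ev$immobility)]))
})
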