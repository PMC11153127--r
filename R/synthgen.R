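#' Synthetic pose-session scenario
#'
#' Describes the study conditions emulated by [gen_pose_session()]: a
#' semi-Markov behaviour program (gamma-distributed dwell times over
#' locomotion, immobility and rearing states), Poisson withdrawal jumps
#' implemented as 0.3 s ballistic displacements with tracking-likelihood
#' dropout, a rigid 11-point body template with isotropic Gaussian
#' tracking jitter, and sporadic single-point confidence dropouts with
#' position spikes. Defaults follow the recording setup emulated here:
#' 40 fps video at 640x480 px of a 20 cm square arena.
#'
#' @param duration_s Session length in seconds.
#' @param fps Frame rate (default 40).
#' @param arena_px Frame size `c(width, height)` in pixels (default
#'   640x480); the arena occupies a centred 400 px square.
#' @param arena_cm Arena side length in cm (default 20).
#' @param state_program Named list of states, each a list with `mean_s`
#'   and `shape` (gamma dwell) and, for moving states, `speed` in cm/s.
#' @param jump_rate Jump events per minute (default 2).
#' @param dropout_likelihood Per-frame, per-point probability of a
#'   spurious low-confidence dropout (default 0.02).
#' @param noise_px SD of the isotropic coordinate jitter in pixels
#'   (default 1.5).
#' @param group_label Group tag carried through to downstream analyses.
#' @param effect_size Scalar shifting the dwell-time means between groups:
#'   immobility dwell is multiplied by `exp(effect_size)` and locomotion
#'   dwell by `exp(-effect_size)` (0 = null condition).
#' @param seed Integer seed; identical scenarios with identical seeds give
#'   identical sessions.
#' @return A list of class `pose_scenario`.
#' @export
pose_scenario <- function(duration_s = 600, fps = 40,
                          arena_px = c(640L, 480L), arena_cm = 20,
                          state_program = list(
                            locomote = list(mean_s = 6, shape = 2, speed = 8),
                            immobile = list(mean_s = 5, shape = 2),
                            rear = list(mean_s = 2, shape = 2, speed = 0.5)
                          ),
                          jump_rate = 2, dropout_likelihood = 0.02,
                          noise_px = 1.5, group_label = "ctl",
                          effect_size = 0, seed = 1L) {
  if (duration_s <= 0) stop("invalid scenario: duration_s must be positive")
  if (fps <= 0) stop("invalid scenario: fps must be positive")
  if (dropout_likelihood < 0 || dropout_likelihood > 1)
    stop("invalid scenario: dropout_likelihood must be in [0, 1]")
  if (jump_rate < 0) stop("invalid scenario: jump_rate must be non-negative")
  if (!length(state_program)) stop("invalid scenario: empty state_program")
  structure(as.list(environment()), class = "pose_scenario")
}

# body template offsets in cm: (longitudinal, lateral) per animal point,
# nose forward (+), tail backward (-)
BODY_TEMPLATE <- matrix(c(
  3.5,  0.0,   # nose
  2.5,  0.8,   # ear_left
  2.5, -0.8,   # ear_right
  1.5,  1.0,   # shoulder_left
  1.5, -1.0,   # shoulder_right
  0.0,  0.0,   # body_centre
  -1.5,  1.0,  # hip_left
  -1.5, -1.0,  # hip_right
  -2.5,  0.0,  # tail_base
  -4.0,  0.0,  # tail_middle
  -5.5,  0.0   # tail_end
), ncol = 2, byrow = TRUE,
dimnames = list(ANIMAL_POINTS, c("long", "lat")))

JUMP_FRAMES_S <- 0.3       # ballistic jump duration
JUMP_PEAK_SPEED <- 60      # cm/s at mid-jump

#' Generate a synthetic pose session with ground truth
#'
#' Simulates a full tracking session according to a [pose_scenario()]:
#' behaviour states are drawn from the semi-Markov program, the body
#' centre follows a state-dependent heading random walk reflected at the
#' arena walls, jumps are overlaid as ballistic out-and-back displacements
#' during which all animal-point likelihoods drop below 0.5, the rigid
#' body template (spine contracted during rearing) is placed along the
#' heading, and tracking jitter plus sporadic dropouts with position
#' spikes are added. The four corner points are static at the arena
#' corners.
#'
#' @param scenario A [pose_scenario()].
#' @return A list: `track` (a [pose_track()]), `truth` (list with `jumps`
#'   and `immobility` data.frames and the per-frame `state` vector), and
#'   `scenario`.
#' @export
gen_pose_session <- function(scenario) {
  stopifnot(inherits(scenario, "pose_scenario"))
  sc <- scenario
  n <- round(sc$duration_s * sc$fps)
  withr::with_seed(sc$seed, {
    # arena geometry: centred square of 400/480*height? fixed 400 px square
    side_px <- 0.833 * min(sc$arena_px)
    cx0 <- sc$arena_px[1] / 2; cy0 <- sc$arena_px[2] / 2
    half <- side_px / 2
    corners <- rbind(corner_tl = c(cx0 - half, cy0 - half),
                     corner_tr = c(cx0 + half, cy0 - half),
                     corner_br = c(cx0 + half, cy0 + half),
                     corner_bl = c(cx0 - half, cy0 + half))
    cm_per_px <- sc$arena_cm / side_px
    px_per_cm <- 1 / cm_per_px

    # --- semi-Markov state sequence ---------------------------------------
    prog <- sc$state_program
    snames <- names(prog)
    dwell_mean <- vapply(snames, function(s) prog[[s]]$mean_s, 0)
    if ("immobile" %in% snames)
      dwell_mean["immobile"] <- dwell_mean["immobile"] * exp(sc$effect_size)
    if ("locomote" %in% snames)
      dwell_mean["locomote"] <- dwell_mean["locomote"] * exp(-sc$effect_size)

    state <- character(n)
    cur <- sample(snames, 1L)
    pos <- 1L
    min_dwell <- round(0.5 * sc$fps)   # bouts shorter than 0.5 s are not
    while (pos <= n) {                 # behaviourally meaningful
      shape <- prog[[cur]]$shape
      d <- stats::rgamma(1L, shape = shape,
                         scale = dwell_mean[[cur]] / shape)
      len <- max(min_dwell, round(d * sc$fps))
      state[pos:min(n, pos + len - 1L)] <- cur
      pos <- pos + len
      nxt <- setdiff(snames, cur)
      cur <- if (length(nxt)) sample(nxt, 1L) else cur
    }

    # --- jump overlay -----------------------------------------------------
    jlen <- max(4L, round(JUMP_FRAMES_S * sc$fps))
    n_jumps <- stats::rpois(1L, sc$jump_rate * sc$duration_s / 60)
    jump_on <- integer(0)
    if (n_jumps > 0L && n > jlen + 2L) {
      cand <- sort(sample.int(n - jlen - 1L, min(n_jumps, n - jlen - 1L)))
      min_gap <- round(2 * sc$fps)
      for (j in cand)
        if (!length(jump_on) || j - jump_on[length(jump_on)] >= min_gap)
          jump_on <- c(jump_on, j)
    }
    for (j in jump_on) state[j:(j + jlen - 1L)] <- "jump"

    # --- per-frame speed (cm/s) and heading -------------------------------
    speed <- numeric(n)
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (b in seq_along(r$values)) {
      st <- r$values[b]
      idx <- starts[b]:ends[b]
      if (st == "jump") {
        prof <- JUMP_PEAK_SPEED * sin(pi * seq_along(idx) / (length(idx) + 1))
        speed[idx] <- prof
      } else if (!is.null(prog[[st]]$speed) && prog[[st]]$speed > 0) {
        sp <- prog[[st]]$speed
        bout_speed <- stats::rgamma(1L, shape = 36, scale = sp / 36)
        speed[idx] <- bout_speed
      }
    }

    dtheta <- stats::rnorm(n, 0, 0.08)
    # jump phase per frame: 0 none, 1 outward, 2 return; jumps launch
    # toward the arena interior so the ballistic displacement is not
    # folded back by the walls
    jphase <- integer(n)
    jump_id <- integer(n)
    for (k in seq_along(jump_on)) {
      j <- jump_on[k]
      idx <- j:(j + jlen - 1L)
      outw <- idx[seq_len(length(idx) %/% 2)]
      jphase[outw] <- 1L
      jphase[setdiff(idx, outw)] <- 2L
      jump_id[idx] <- k
    }
    jump_jitter <- stats::rnorm(length(jump_on), 0, 0.2)

    step_px <- speed / sc$fps * px_per_cm

    # integrate with reflection at the arena walls (3 cm body margin);
    # the heading reflects with the position, so the animal bounces off
    # walls instead of being pinned against them
    margin <- 3 * px_per_cm
    xlim <- c(cx0 - half + margin, cx0 + half - margin)
    ylim <- c(cy0 - half + margin, cy0 + half - margin)
    cxv <- numeric(n); cyv <- numeric(n)
    theta <- numeric(n)
    px <- cx0; py <- cy0
    ang <- stats::runif(1L, 0, 2 * pi)
    jump_dir <- NA_real_
    buf <- 1.5 * px_per_cm   # start steering away this far from a wall
    for (i in seq_len(n)) {
      if (jphase[i] == 0L) {
        # the heading only changes while the animal actually moves: an
        # immobile mouse does not swing its body around
        if (step_px[i] > 0) {
          # a bout that starts next to a wall sets off toward the interior
          if ((i == 1L || step_px[i - 1L] == 0) &&
              (px < xlim[1] + buf || px > xlim[2] - buf ||
               py < ylim[1] + buf || py > ylim[2] - buf))
            ang <- atan2(cy0 - py, cx0 - px)
          ang <- ang + dtheta[i]
          # smooth wall avoidance: turn toward the centre when close to
          # a wall, so locomotion never degenerates into a wall zigzag;
          # the turn rate scales with speed (finite turning radius)
          if (px < xlim[1] + buf || px > xlim[2] - buf ||
              py < ylim[1] + buf || py > ylim[2] - buf) {
            d <- (atan2(cy0 - py, cx0 - px) - ang + pi) %% (2 * pi) - pi
            ang <- ang + sign(d) * min(abs(d), 0.04 * speed[i])
          }
        }
      } else {
        if (jphase[i] == 1L && (i == 1L || jump_id[i - 1L] != jump_id[i]))
          jump_dir <- atan2(cy0 - py, cx0 - px) + jump_jitter[jump_id[i]]
        ang <- if (jphase[i] == 1L) jump_dir else jump_dir + pi
      }
      px <- px + step_px[i] * cos(ang)
      py <- py + step_px[i] * sin(ang)
      if (px < xlim[1]) { px <- 2 * xlim[1] - px; ang <- pi - ang }
      if (px > xlim[2]) { px <- 2 * xlim[2] - px; ang <- pi - ang }
      if (py < ylim[1]) { py <- 2 * ylim[1] - py; ang <- -ang }
      if (py > ylim[2]) { py <- 2 * ylim[2] - py; ang <- -ang }
      cxv[i] <- px; cyv[i] <- py
      theta[i] <- ang
    }

    # --- body template ----------------------------------------------------
    hx <- cos(theta); hy <- sin(theta)
    contract <- ifelse(state == "rear", 0.45, 1)
    x <- matrix(0, n, length(ALL_POINTS),
                dimnames = list(NULL, ALL_POINTS))
    y <- x
    for (p in ANIMAL_POINTS) {
      lon <- BODY_TEMPLATE[p, "long"] * px_per_cm * contract
      lat <- BODY_TEMPLATE[p, "lat"] * px_per_cm
      # walls physically constrain the body: points that would poke
      # beyond the arena (e.g. the tail against a wall) are pressed to it
      x[, p] <- pmin(pmax(cxv + lon * hx - lat * hy, cx0 - half + 2),
                     cx0 + half - 2)
      y[, p] <- pmin(pmax(cyv + lon * hy + lat * hx, cy0 - half + 2),
                     cy0 + half - 2)
    }
    x[, ANIMAL_POINTS] <- x[, ANIMAL_POINTS] +
      matrix(stats::rnorm(n * 11L, 0, sc$noise_px), n, 11L)
    y[, ANIMAL_POINTS] <- y[, ANIMAL_POINTS] +
      matrix(stats::rnorm(n * 11L, 0, sc$noise_px), n, 11L)
    for (p in CORNER_POINTS) {
      x[, p] <- corners[p, 1] + stats::rnorm(n, 0, 0.3)
      y[, p] <- corners[p, 2] + stats::rnorm(n, 0, 0.3)
    }

    # --- likelihoods ------------------------------------------------------
    lik <- matrix(pmin(1, 1 - abs(stats::rnorm(n * length(ALL_POINTS),
                                               0, 0.008))),
                  n, length(ALL_POINTS), dimnames = list(NULL, ALL_POINTS))
    # sporadic dropouts with position spikes
    if (sc$dropout_likelihood > 0) {
      drop <- matrix(stats::runif(n * 11L) < sc$dropout_likelihood, n, 11L)
      nd <- sum(drop)
      if (nd) {
        lik[, ANIMAL_POINTS][drop] <- stats::runif(nd, 0, 0.04)
        spike <- function(k) (stats::runif(k, 20, 60)) *
          sign(stats::runif(k, -1, 1))
        x[, ANIMAL_POINTS][drop] <- x[, ANIMAL_POINTS][drop] + spike(nd)
        y[, ANIMAL_POINTS][drop] <- y[, ANIMAL_POINTS][drop] + spike(nd)
      }
    }
    # jump dropout: whole-body low confidence on the core of the jump
    for (j in jump_on) {
      core <- (j + 2L):(j + jlen - 3L)
      lik[core, ANIMAL_POINTS] <-
        stats::runif(length(core) * 11L, 0.05, 0.45)
    }

    track <- pose_track(x, y, lik, fps = sc$fps, frame_px = sc$arena_px)

    jumps <- data.frame(onset = jump_on, offset = jump_on + jlen - 1L)
    jumps$onset_s <- (jumps$onset - 1L) / sc$fps
    jumps$offset_s <- (jumps$offset - 1L) / sc$fps
    # ground-truth immobility = centroid quiescence: states whose
    # programmed centroid speed is (near) zero, i.e. immobile and rear
    quiescent <- vapply(snames, function(s)
      is.null(prog[[s]]$speed) || prog[[s]]$speed < 2, TRUE)
    imm <- runs_of(state %in% snames[quiescent])
    imm$duration_s <- (imm$offset - imm$onset + 1L) / sc$fps

    list(track = track,
         truth = list(jumps = jumps, immobility = imm, state = state),
         scenario = sc)
  })
}

#' Synthetic photometry scenario
#'
#' Conditions for [gen_photometry_session()]: an exponentially decaying
#' baseline drift shared by both channels, an Ornstein-Uhlenbeck motion
#' artifact added to both channels (correlated noise that the isosbestic
#' regression must remove), Poisson calcium transients with a
#' double-exponential kernel on the 470 nm channel only, an optional slow
#' injection response, and white instrument noise per channel. Transient
#' and injection amplitudes are in dF/F units; transients occur throughout
#' the recording, so the baseline window contains spontaneous activity,
#' as real recordings do.
#'
#' @param duration_s Recording length in seconds (default 1500: 5 min
#'   baseline + 20 min post-injection).
#' @param rate_hz Sampling rate (default 20).
#' @param f0 Static 470 nm fluorescence level, a.u. (default 100).
#' @param drift `c(amplitude, tau_s)` of the baseline decay (a.u.).
#' @param motion_gain_470,motion_gain_405 Gains applied to the shared
#'   artifact in each channel.
#' @param artifact `c(sd, tau_s)` of the OU artifact (a.u.).
#' @param transient_rate Transients per minute (default 5, so the
#'   baseline window reliably contains spontaneous activity, as real
#'   recordings do).
#' @param transient_kernel `c(rise_s, decay_s, amplitude)` with amplitude
#'   in dF/F units (default 0.1 s, 0.5 s, 0.05).
#' @param injection_response `NULL` or `c(onset_s, amplitude, sign,
#'   decay_tau_s)` with amplitude in dF/F units.
#' @param noise_sd Per-channel white-noise SD, a.u. (default 0.1).
#' @param baseline_s Length of the pre-injection baseline window
#'   (default 300 s, i.e. 5 min).
#' @param seed Integer seed.
#' @return A list of class `photometry_scenario`.
#' @export
photometry_scenario <- function(duration_s = 1500, rate_hz = 20, f0 = 100,
                                drift = c(amplitude = 5, tau = 600),
                                motion_gain_470 = 1, motion_gain_405 = 1,
                                artifact = c(sd = 1, tau = 2),
                                transient_rate = 5,
                                transient_kernel = c(rise = 0.1, decay = 0.5,
                                                     amplitude = 0.05),
                                injection_response = NULL,
                                noise_sd = 0.1, baseline_s = 300,
                                seed = 1L) {
  if (duration_s <= 0) stop("invalid scenario: duration_s must be positive")
  if (rate_hz <= 0) stop("invalid scenario: rate_hz must be positive")
  if (transient_kernel[["rise"]] <= 0 || transient_kernel[["decay"]] <= 0)
    stop("invalid scenario: kernel time constants must be positive")
  if (drift[["tau"]] <= 0 || artifact[["tau"]] <= 0)
    stop("invalid scenario: time constants must be positive")
  if (transient_rate < 0 || noise_sd < 0)
    stop("invalid scenario: rates and noise must be non-negative")
  structure(as.list(environment()), class = "photometry_scenario")
}

# double-exponential transient kernel, peak-normalized to 1
transient_kernel_shape <- function(t, rise, decay) {
  k <- (1 - exp(-t / rise)) * exp(-t / decay)
  k / max(k)
}

#' Generate a synthetic photometry recording with ground truth
#'
#' @param scenario A [photometry_scenario()].
#' @return A list: `recording` (a [photometry_recording()] with the
#'   injection marker if present) and `truth` (data.frame of transient
#'   `onset_s`, `peak_s`, `amplitude`).
#' @export
gen_photometry_session <- function(scenario) {
  stopifnot(inherits(scenario, "photometry_scenario"))
  sc <- scenario
  n <- round(sc$duration_s * sc$rate_hz)
  dt <- 1 / sc$rate_hz
  withr::with_seed(sc$seed, {
    t <- (seq_len(n) - 1L) * dt
    drift <- sc$drift[["amplitude"]] * exp(-t / sc$drift[["tau"]])
    base470 <- sc$f0 + drift

    # OU artifact shared by both channels
    a <- numeric(n)
    rho <- exp(-dt / sc$artifact[["tau"]])
    innov_sd <- sc$artifact[["sd"]] * sqrt(1 - rho^2)
    z <- stats::rnorm(n)
    for (i in 2:n) a[i] <- a[i - 1L] * rho + innov_sd * z[i]

    # transients (dF/F units) throughout the recording
    n_tr <- stats::rpois(1L, sc$transient_rate * sc$duration_s / 60)
    onsets <- sort(stats::runif(n_tr, 0, sc$duration_s - 3))
    kern_t <- seq(0, 5 * sc$transient_kernel[["decay"]], by = dt)
    kern <- transient_kernel_shape(kern_t, sc$transient_kernel[["rise"]],
                                   sc$transient_kernel[["decay"]]) *
      sc$transient_kernel[["amplitude"]]
    dff_sig <- numeric(n)
    for (o in onsets) {
      i0 <- round(o / dt) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      dff_sig[idx] <- dff_sig[idx] + kern[seq_along(idx)]
    }
    peak_lag <- (which.max(kern) - 1L) * dt

    markers <- list()
    if (!is.null(sc$injection_response)) {
      ir <- sc$injection_response
      on <- ir[[1]]; amp <- ir[[2]]; sgn <- ir[[3]]; tau <- ir[[4]]
      tt <- pmax(t - on, 0)
      dff_sig <- dff_sig + ifelse(t >= on,
                                  sgn * amp * (1 - exp(-tt / 30)) *
                                    exp(-tt / tau), 0)
      markers$injection <- on
    }

    f470 <- base470 * (1 + dff_sig) + sc$motion_gain_470 * a +
      stats::rnorm(n, 0, sc$noise_sd)
    f405 <- 10 + base470 + sc$motion_gain_405 * a +
      stats::rnorm(n, 0, sc$noise_sd)

    rec <- photometry_recording(t, f470, f405,
                                baseline_window = c(0, min(sc$baseline_s,
                                                           t[n])),
                                markers = markers)
    truth <- data.frame(onset_s = onsets,
                        peak_s = onsets + peak_lag,
                        amplitude = rep(sc$transient_kernel[["amplitude"]],
                                        length(onsets)))
    list(recording = rec, truth = truth, scenario = sc)
  })
}

#' Generate a synthetic dose-response table
#'
#' Per-subject responses on a four-parameter logistic curve with
#' multiplicative Gaussian noise, truncated at zero:
#' `response = logistic4(dose) * max(0, 1 + cv * z)`.
#'
#' @param doses Dose vector (non-negative; one response per subject and
#'   dose).
#' @param n_subjects Number of subjects.
#' @param top,bottom,ic50,hill Generating curve parameters
#'   (see [logistic4()]).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return data.frame with `subject`, `dose`, `response`.
#' @export
gen_dose_response <- function(doses, n_subjects = 9L, top = 1, bottom = 0,
                              ic50 = 100, hill = -1, cv = 0.1, seed = 1L) {
  if (!length(doses)) stop("empty dose list")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (cv < 0) stop("cv must be non-negative")
  withr::with_seed(seed, {
    tab <- expand.grid(subject = paste0("S", seq_len(n_subjects)),
                       dose = doses, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    mu <- logistic4(tab$dose, top, bottom, ic50, hill)
    tab$response <- pmax(0, mu * (1 + cv * stats::rnorm(nrow(tab))))
    tab
  })
}

#' Generate a three-compartment occupancy track
#'
#' Builds a centroid track through a three-compartment chamber (two choice
#' compartments joined by a corridor) whose per-compartment dwell times
#' match the requested times to within one frame. Time is spent in
#' contiguous visits ordered target / corridor / other / corridor.
#'
#' @param times Named numeric vector of dwell times in seconds; unnamed
#'   vectors of length 3 are taken as `c(target, other, corridor)`.
#' @param fps Frame rate (default 40).
#' @param seed Seed for the within-compartment random walk.
#' @return data.frame with `frame`, `t`, `x`, `y` (cm) and `compartment`;
#'   chamber geometry in `attr(, "geometry")`.
#' @export
gen_preference_session <- function(times, fps = 40, seed = 1L) {
  if (is.null(names(times))) {
    if (length(times) != 3L)
      stop("unnamed times must have length 3: target, other, corridor")
    names(times) <- c("target", "other", "corridor")
  }
  if (any(times < 0)) stop("times must be non-negative")
  if (sum(times) <= 0) stop("total time is zero")
  if (fps <= 0) stop("fps must be positive")
  frames <- round(times * fps)
  comps <- names(times)
  corridor <- if ("corridor" %in% comps) "corridor" else comps[3L]
  choice <- setdiff(comps, corridor)

  # chamber: two 25 cm compartments flanking a 10 cm corridor
  geom <- list(x_range = stats::setNames(
    list(c(0, 25), c(35, 60), c(25, 35)),
    c(choice, corridor)), width_cm = 20)

  half_corr <- c(floor(frames[[corridor]] / 2),
                 ceiling(frames[[corridor]] / 2))
  blocks <- list(c(choice[1L], frames[[choice[1L]]]),
                 c(corridor, half_corr[1L]),
                 c(choice[2L], frames[[choice[2L]]]),
                 c(corridor, half_corr[2L]))
  comp_seq <- unlist(lapply(blocks, function(b)
    rep(b[1L], as.integer(b[2L]))))
  n <- length(comp_seq)
  withr::with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    for (cmp in unique(comp_seq)) {
      idx <- which(comp_seq == cmp)
      xr <- geom$x_range[[cmp]]
      x[idx] <- pmin(xr[2], pmax(xr[1], cumsum(stats::rnorm(length(idx),
        0, 0.3)) %% diff(xr) + xr[1]))
      y[idx] <- stats::runif(length(idx), 2, geom$width_cm - 2)
    }
    out <- data.frame(frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) / fps,
                      x = x, y = y, compartment = comp_seq)
    attr(out, "geometry") <- geom
    attr(out, "fps") <- fps
    out
  })
}
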