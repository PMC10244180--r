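#' Default start-transition matrix for the ethogram simulator
#'
#' A 7x7 row-stochastic matrix qualitatively mirroring the egg-laying
#' sequence: a pe/walk exploration loop, walk -> bend, bend -> burrow,
#' burrow self-transitions and abort routes, deterministic
#' egg_out -> detach, and a detach -> groom dominated post phase. The
#' numbers are free simulator parameters, not estimates.
#'
#' @return Row-stochastic 7x7 matrix over [behavior_labels()].
#' @export
default_transition_matrix <- function() {
  labs <- behavior_labels()
  m <- matrix(0, 7, 7, dimnames = list(labs, labs))
  m["pe", ] <- c(0.20, 0.50, 0.15, 0, 0, 0, 0.15)
  m["walk", ] <- c(0.35, 0.20, 0.30, 0, 0, 0, 0.15)
  m["bend", ] <- c(0.05, 0.20, 0.05, 0.70, 0, 0, 0)
  m["burrow", ] <- c(0.05, 0.10, 0.20, 0.45, 0.20, 0, 0)
  m["egg_out", ] <- c(0, 0, 0, 0, 0, 1, 0)
  m["detach", ] <- c(0, 0, 0, 0, 0, 0, 1)
  m["groom", ] <- c(0.30, 0.45, 0, 0, 0, 0, 0.25)
  m
}

default_dwell_params <- function() {
  # gamma (shape, scale) of start-to-start gaps, seconds
  list(pe = c(2, 0.5), walk = c(2, 1.5), bend = c(2, 1.0),
       burrow = c(2, 0.3), egg_out = c(2, 0.15), detach = c(2, 0.4),
       groom = c(2, 1.5))
}

#' Simulate egg-laying ethograms from a semi-Markov start-event chain
#'
#' Draws, per event, an ordered sequence of behavior onsets from a
#' start-to-start transition matrix with gamma-distributed onset-to-onset
#' gaps, then paints a frame-wise multi-label activity matrix honoring the
#' overlap rules (bend persists through burrow/egg_out/detach; a label
#' restarting closes its previous bout one frame earlier, so every chain
#' item yields exactly one bout onset and the chain is exactly recoverable
#' from the ethogram). Burrow bouts carry cycle annotations at
#' `cycle_rate`; the bout's duration is its cycle count over the rate. Each
#' event carries one egg_out, placed at the end of a persistent burrow
#' episode; after it the chain proceeds through the reset components and a
#' short geometric number of further exploratory items.
#'
#' When `p_abort_per_cycle` is supplied, burrow outcomes are governed
#' cycle-by-cycle instead of by the matrix row: after each cycle the
#' episode aborts with that probability, and expels if `n_expel_cycles` is
#' reached first (0 means every episode expels).
#'
#' @param n_events Number of independent egg-laying events.
#' @param transition_matrix 7x7 row-stochastic start-transition matrix.
#' @param dwell Named list of per-label gamma `(shape, scale)` gap
#'   parameters in seconds.
#' @param cycle_rate Burrow cycles per second (default 1.5).
#' @param p_abort_per_cycle Optional per-cycle abort probability.
#' @param n_expel_cycles Cycle count reaching expulsion under the
#'   per-cycle mode (default 5).
#' @param fps Frame rate (default 20).
#' @param n_flies Events are distributed round-robin over this many fly
#'   ids (default 1).
#' @param initial_distribution First-label distribution (default an even
#'   pe/walk split).
#' @param max_items Safety cap on pre-expulsion chain length (default 500).
#' @param post_continue Probability of continuing the chain after each
#'   post-groom item (default 0.6).
#' @param with_location Attach a location track (mm) that advances during
#'   walking (default `FALSE`).
#' @param walk_speed_mm_s Locomotion speed for the location track.
#' @param seed Integer seed; output is a pure function of the parameters
#'   and the seed.
#' @return List with `ethograms` (length `n_events`) and `ground_truth`
#'   (the matrix, per-event item tables, episode tables).
#' @export
simulate_ethogram <- function(n_events = 1,
                              transition_matrix = default_transition_matrix(),
                              dwell = default_dwell_params(),
                              cycle_rate = 1.5,
                              p_abort_per_cycle = NULL,
                              n_expel_cycles = 5,
                              fps = 20, n_flies = 1,
                              initial_distribution = NULL,
                              max_items = 500, post_continue = 0.85,
                              with_location = FALSE,
                              walk_speed_mm_s = 3,
                              seed = 1) {
  labs <- behavior_labels()
  P <- transition_matrix
  if (!all(abs(rowSums(P) - 1) < 1e-8)) stop("matrix rows must sum to 1")
  if (is.null(initial_distribution))
    initial_distribution <- stats::setNames(c(.5, .5, 0, 0, 0, 0, 0), labs)
  with_seed(seed, {
    ethos <- vector("list", n_events)
    items_gt <- vector("list", n_events)
    episodes_gt <- vector("list", n_events)
    for (ev in seq_len(n_events)) {
      sim <- simulate_one_event(P, dwell, cycle_rate, p_abort_per_cycle,
                                n_expel_cycles, fps, initial_distribution,
                                max_items, post_continue, with_location,
                                walk_speed_mm_s)
      sim$e$fly_id <- sprintf("fly%02d", ((ev - 1L) %% n_flies) + 1L)
      sim$e$event_id <- sprintf("event%03d", ev)
      ethos[[ev]] <- sim$e
      items_gt[[ev]] <- sim$items
      episodes_gt[[ev]] <- sim$episodes
    }
    list(ethograms = ethos,
         ground_truth = list(transition_matrix = P, items = items_gt,
                             episodes = episodes_gt))
  })
}

simulate_one_event <- function(P, dwell, cycle_rate, p_abort, n_expel,
                               fps, init, max_items, post_continue,
                               with_location, walk_speed) {
  labs <- behavior_labels()
  draw_next <- function(cur) sample(labs, 1, prob = P[cur, ])
  seq_labs <- character(0)
  burrow_cycles <- integer(0)  # cycles per burrow item, in order
  cur <- sample(labs, 1, prob = init)
  repeat {
    if (cur == "burrow") {
      if (!is.null(p_abort)) {
        nc <- 0L
        repeat {
          nc <- nc + 1L
          if (nc >= n_expel) { nxt <- "egg_out"; break }
          if (stats::runif(1) < p_abort) {
            row <- P["burrow", ]; row["egg_out"] <- 0
            if (sum(row) == 0) row["walk"] <- 1
            nxt <- sample(labs, 1, prob = row / sum(row))
            break
          }
        }
      } else {
        nxt <- draw_next(cur)
        nc <- if (nxt == "egg_out") 3L + stats::rpois(1, 2)
              else max(1L, 1L + stats::rpois(1, 2))
      }
      burrow_cycles <- c(burrow_cycles, nc)
    } else {
      nxt <- draw_next(cur)
    }
    seq_labs <- c(seq_labs, cur)
    if (cur == "egg_out" || length(seq_labs) >= max_items) {
      if (cur != "egg_out") break
      # post-expulsion continuation
      cur <- nxt
      seen_groom <- FALSE
      repeat {
        seq_labs <- c(seq_labs, cur)
        if (cur == "burrow")  # post-phase burrowing never expels again
          burrow_cycles <- c(burrow_cycles,
                             max(1L, 1L + stats::rpois(1, 2)))
        if (cur == "groom") seen_groom <- TRUE
        # the event's observation window closes geometrically once the
        # reset phase (groom) is reached, and immediately when a new bend
        # re-initiates deposition; both stopping rules depend only on the
        # emitted history, leaving row-wise transition estimates unbiased
        if (cur == "bend") break
        if (seen_groom && stats::runif(1) > post_continue) break
        if (length(seq_labs) >= max_items) break
        nxt2 <- draw_next(cur)
        if (cur == "burrow") while (nxt2 == "egg_out") nxt2 <- draw_next(cur)
        cur <- nxt2
      }
      break
    }
    cur <- nxt
  }
  # onset times (frames)
  nI <- length(seq_labs)
  gaps <- numeric(nI)
  bi <- 0L
  for (i in seq_len(nI)) {
    lb <- seq_labs[i]
    if (lb == "burrow") {
      bi <- bi + 1L
      gaps[i] <- burrow_cycles[bi] / cycle_rate +
        stats::rgamma(1, dwell$burrow[1], scale = dwell$burrow[2])
    } else {
      gaps[i] <- stats::rgamma(1, dwell[[lb]][1], scale = dwell[[lb]][2])
    }
  }
  gap_f <- pmax(2L, round(gaps * fps))
  onset <- cumsum(c(0L, gap_f[-nI]))
  n_frames <- onset[nI] + gap_f[nI] + 5L
  # paint activity with overlap rules
  a <- matrix(FALSE, n_frames, 7L, dimnames = list(NULL, labs))
  open <- stats::setNames(rep(NA_integer_, 7L), labs)  # open bout starts
  close_label <- function(lb, at) {
    if (!is.na(open[[lb]]) && at > open[[lb]])
      a[(open[[lb]] + 1L):at, lb] <<- TRUE
    open[[lb]] <<- NA_integer_
  }
  persists <- function(lb, x)  # does open label lb persist when x starts?
    (lb == "bend" && x %in% c("burrow", "egg_out", "detach")) ||
    (lb == "burrow" && x == "egg_out")
  for (i in seq_len(nI)) {
    x <- seq_labs[i]; f <- onset[i]
    if (!is.na(open[[x]])) close_label(x, f - 1L)
    for (lb in labs[!is.na(open)])
      if (lb != x && !persists(lb, x)) close_label(lb, f)
    open[[x]] <- f
    if (x == "egg_out") {
      close_label("egg_out", f + 1L)
      if (!is.na(open[["burrow"]])) close_label("burrow", f + 1L)
    }
  }
  for (lb in labs[!is.na(open)]) close_label(lb, onset[nI] + gap_f[nI])
  # cycle frames within burrow bouts
  cyc <- integer(0)
  bi <- 0L
  episodes <- NULL
  for (i in seq_len(nI)) {
    if (seq_labs[i] != "burrow") next
    bi <- bi + 1L
    nc <- burrow_cycles[bi]
    f0 <- onset[i]
    f_end <- f0
    while (f_end < n_frames && a[f_end + 1L, "burrow"]) f_end <- f_end + 1L
    cf <- f0 + pmin(round((seq_len(nc) - 0.5) / cycle_rate * fps),
                    f_end - f0 - 1L)
    cf <- unique(pmax(cf, f0))
    cyc <- c(cyc, cf)
    expel <- i < nI && seq_labs[i + 1L] == "egg_out"
    episodes <- rbind(episodes,
                      data.frame(start = f0, end = f_end, n_cycles = length(cf),
                                 outcome = if (expel) "expel" else "abort"))
  }
  egg_f <- onset[match("egg_out", seq_labs)]
  loc <- NULL
  if (with_location) {
    step <- numeric(n_frames)
    step[which(a[, "walk"])] <- walk_speed / fps
    heading <- cumsum(stats::rnorm(n_frames, 0, 0.1))
    loc <- cbind(cumsum(step * cos(heading)), cumsum(step * sin(heading)))
  }
  e <- ethogram(a, fps = fps,
                egg_out_frame = if (is.na(egg_f)) NULL else egg_f,
                cycle_frames = sort(cyc), location = loc)
  list(e = e, items = data.frame(label = seq_labs, frame = onset),
       episodes = episodes)
}

#' Simulate a keypoint track (and ovipositor ROI intensity) for an ethogram
#'
#' Renders the behaviors of an ethogram as keypoint kinematics: walking
#' translates the whole animal at `walk_speed_mm_s`; bending ramps the
#' abdominal line angle; burrowing drives an ovipositor-ROI intensity
#' oscillation (and an A5-stripe oscillation) whose frequency decreases
#' linearly across the episode from `burrow_freq_start` to
#' `burrow_freq_end` Hz (set them equal for a fixed tone); proboscis
#' extension displaces the proboscis tip; egg-emergence confidence ramps
#' to 1 around egg_out. Gaussian positional jitter is added to every
#' keypoint.
#'
#' @param e An `ethogram`.
#' @param px_per_mm Calibration (default 20).
#' @param walk_speed_mm_s Walking speed (default 3).
#' @param bend_angle_rad Peak abdominal bend angle (default 0.8).
#' @param burrow_freq_start,burrow_freq_end Episode oscillation frequency
#'   sweep in Hz (defaults 1.8 and 0.9).
#' @param osc_amp_px A5 oscillation amplitude (default 3 px).
#' @param intensity_baseline,intensity_amp ROI intensity baseline and
#'   oscillation amplitude (defaults 100 and 30).
#' @param jitter_px Keypoint jitter sd (default 0.2 px; 0 disables).
#' @param noise_intensity ROI intensity noise sd (default 1).
#' @param seed Integer seed.
#' @return List with `track` (a `keypoint_track`), `ovi_intensity` and
#'   `ground_truth` (per-frame motif labels: the highest-priority active
#'   behavior, `"none"` when idle).
#' @export
simulate_keypoints <- function(e, px_per_mm = 20, walk_speed_mm_s = 3,
                               bend_angle_rad = 0.8,
                               burrow_freq_start = 1.8,
                               burrow_freq_end = 0.9,
                               osc_amp_px = 3,
                               intensity_baseline = 100, intensity_amp = 30,
                               jitter_px = 0.2, noise_intensity = 1,
                               seed = 1) {
  validate_ethogram(e)
  n <- nrow(e$activity)
  fps <- e$fps
  parts <- feature_bodyparts()
  base <- rbind(scutellum = c(30, 0), ocellus = c(0, 0),
                proboscis_tip = c(-10, 0), stripe_A2 = c(45, 0),
                stripe_A5 = c(60, 0), stripe_A6 = c(70, 0),
                leg_T1 = c(10, 12), leg_T2 = c(20, 14), leg_T3 = c(30, 16),
                ovipositor = c(75, -2), T6_edge = c(72, 1),
                egg_tip = c(78, -3), analia_base = c(76, 2))[parts, ]
  with_seed(seed, {
    # whole-body translation while walking
    step <- ifelse(e$activity[, "walk"], walk_speed_mm_s * px_per_mm / fps, 0)
    ox <- cumsum(step)
    # abdominal bend angle ramp (1-s rise, hold)
    bend <- numeric(n)
    bb <- to_bouts(e); bb <- bb[bb$label == "bend", , drop = FALSE]
    for (i in seq_len(nrow(bb))) {
      idx <- (bb$start[i] + 1L):bb$end[i]
      ramp <- pmin(seq_along(idx) / fps, 1)
      bend[idx] <- bend_angle_rad * ramp
    }
    # burrow oscillation phase with a linear within-episode frequency sweep
    phase <- numeric(n); inburrow <- logical(n)
    eb <- to_bouts(e); eb <- eb[eb$label == "burrow", , drop = FALSE]
    freq_gt <- rep(NA_real_, n)
    for (i in seq_len(nrow(eb))) {
      idx <- (eb$start[i] + 1L):eb$end[i]
      u <- (seq_along(idx) - 1) / max(length(idx) - 1, 1)
      f <- burrow_freq_start + (burrow_freq_end - burrow_freq_start) * u
      phase[idx] <- 2 * pi * cumsum(f) / fps
      freq_gt[idx] <- f
      inburrow[idx] <- TRUE
    }
    osc <- ifelse(inburrow, sin(phase), 0)
    xy <- array(0, c(n, length(parts), 2L),
                dimnames = list(NULL, parts, c("x", "y")))
    for (p in parts) {
      xy[, p, "x"] <- base[p, 1] + ox
      xy[, p, "y"] <- base[p, 2]
    }
    # bend rotates abdominal landmarks about stripe_A2
    abd <- c("stripe_A5", "stripe_A6", "ovipositor", "T6_edge", "egg_tip",
             "analia_base")
    for (p in abd) {
      r <- base[p, ] - base["stripe_A2", ]
      xy[, p, "x"] <- base["stripe_A2", 1] + ox +
        r[1] * cos(bend) - r[2] * sin(bend)
      xy[, p, "y"] <- base["stripe_A2", 2] +
        r[1] * sin(bend) + r[2] * cos(bend)
    }
    xy[, "stripe_A5", "y"] <- xy[, "stripe_A5", "y"] + osc_amp_px * osc
    # proboscis extension
    pe_on <- e$activity[, "pe"]
    xy[, "proboscis_tip", "x"] <- xy[, "proboscis_tip", "x"] -
      6 * stats::filter(as.numeric(pe_on), rep(1 / 3, 3), sides = 2,
                        circular = TRUE)
    if (jitter_px > 0)
      xy <- xy + stats::rnorm(length(xy), 0, jitter_px)
    conf <- matrix(1, n, length(parts), dimnames = list(NULL, parts))
    pegg <- rep(0.01, n)
    if (!is.null(e$egg_out_frame)) {
      f <- e$egg_out_frame
      up <- max(0L, f - fps):f
      pegg[up + 1L] <- 0.01 + (1 - 0.01) * seq(0, 1, length.out = length(up))
      dn <- f:min(n - 1L, f + round(fps / 2))
      pegg[dn + 1L] <- 1
    }
    conf[, "egg_tip"] <- pegg
    ovi <- intensity_baseline + intensity_amp * osc +
      stats::rnorm(n, 0, noise_intensity)
    motif <- rep("none", n)
    for (lb in rev(c("egg_out", "burrow", "bend", "detach", "groom",
                     "pe", "walk")))
      motif[e$activity[, lb]] <- lb
    list(track = keypoint_track(xy, conf, fps = fps, px_per_mm = px_per_mm),
         ovi_intensity = ovi,
         ground_truth = list(motif = motif, burrow_freq = freq_gt))
  })
}

#' Simulate a paired fluorescence/behavior recording
#'
#' Green-channel fluorescence is a baseline plus double-exponential calcium
#' transients at the supplied event onsets, a slow sinusoidal drift shared
#' with the red channel, and white noise; the red (anatomical) channel
#' carries no transients. The transient kernel is normalized on the sample
#' grid so its peak dF/F equals `amplitude` exactly. Tracked distances are
#' rendered as steps at the event onsets: the T6-egg distance rises at
#' expulsion-type events (returning after incomplete ones), the
#' T6-ovipositor distance rises at extrusion events, and the T6-analia
#' reference stays constant.
#'
#' @param onsets Event onset times (s).
#' @param types Character vector (`"incomplete_expulsion"`,
#'   `"complete_expulsion"`, `"ovipositor_extrusion"`), recycled.
#' @param duration_s Recording length (default 180 s).
#' @param fps Acquisition rate (default 10).
#' @param amplitude Transient peak dF/F (default 1).
#' @param tau_rise,tau_decay Kernel time constants in s (defaults 0.1,
#'   0.5).
#' @param baseline_F Baseline fluorescence (default 100).
#' @param noise_sd Fluorescence noise sd (default 1; 0 disables).
#' @param drift Slow drift amplitude as a fraction of baseline
#'   (default 0.02).
#' @param n_roi Number of ROIs sharing the event times (default 1).
#' @param step_px Distance step height (default 15 px).
#' @param dist_noise_sd Distance trace noise sd in px (default 0.5).
#' @param seed Integer seed.
#' @return List with `recording` (a `fluorescence_recording`),
#'   `distances` (raw px traces `t6_egg`, `t6_ovi`, `t6_analia`) and
#'   `ground_truth` (onsets and types).
#' @export
simulate_fluorescence <- function(onsets, types = "complete_expulsion",
                                  duration_s = 180, fps = 10,
                                  amplitude = 1, tau_rise = 0.1,
                                  tau_decay = 0.5, baseline_F = 100,
                                  noise_sd = 1, drift = 0.02, n_roi = 1,
                                  step_px = 15, dist_noise_sd = 0.5,
                                  seed = 1) {
  if (noise_sd < 0 || dist_noise_sd < 0) stop("negative noise sd")
  if (length(onsets) && any(onsets < 0 | onsets > duration_s))
    stop("onsets outside recording")
  types <- rep_len(types, length(onsets))
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  with_seed(seed, {
    sig <- numeric(n)
    for (on in onsets) {
      tt <- t - on
      k <- ifelse(tt >= 0, exp(-tt / tau_decay) - exp(-tt / tau_rise), 0)
      if (max(k) > 0) sig <- sig + amplitude * k / max(k)
    }
    dr <- drift * sin(2 * pi * t / duration_s)
    green <- vapply(seq_len(n_roi), function(r)
      baseline_F * (1 + sig + dr) + stats::rnorm(n, 0, noise_sd),
      numeric(n))
    red <- vapply(seq_len(n_roi), function(r)
      baseline_F * (1 + dr) + stats::rnorm(n, 0, noise_sd), numeric(n))
    green <- pmax(green, 0)
    step_win <- function(on, hold_s) {
      # instantaneous rise/fall: a tracked egg advance is sub-frame at
      # typical acquisition rates
      w <- numeric(n)
      w[t >= on & t <= on + hold_s] <- 1
      w
    }
    t6_egg <- rep(20, n); t6_ovi <- rep(25, n)
    for (i in seq_along(onsets)) {
      if (types[i] == "ovipositor_extrusion") {
        t6_ovi <- t6_ovi + step_px * step_win(onsets[i], 2)
      } else if (types[i] == "incomplete_expulsion") {
        t6_egg <- t6_egg + step_px * step_win(onsets[i], 2)
      } else {
        w <- numeric(n)
        w[t >= onsets[i]] <- 1
        t6_egg <- t6_egg + step_px * w
      }
    }
    t6_egg <- t6_egg + stats::rnorm(n, 0, dist_noise_sd)
    t6_ovi <- t6_ovi + stats::rnorm(n, 0, dist_noise_sd)
    t6_analia <- 50 + stats::rnorm(n, 0, dist_noise_sd)
    list(recording = fluorescence_recording(green, red, fps = fps),
         distances = list(t6_egg = t6_egg, t6_ovi = t6_ovi,
                          t6_analia = t6_analia),
         ground_truth = list(onsets = onsets, types = types))
  })
}

#' Simulate per-fly egg records across substrate firmness levels
#'
#' Per firmness level, each fly lays a Poisson-distributed number of eggs
#' whose depth categories are drawn so that twice the depth score is
#' Binomial(2, p) with p = `mean_depth` for that level (hence the pooled
#' mean normalized depth has an exact binomial sampling law). Wall
#' deposition and spontaneous drops are independent Bernoulli marks.
#'
#' @param firmness Substrate agarose percentages.
#' @param mean_depth Generating mean normalized depth per level (same
#'   length as `firmness`).
#' @param n_flies Flies per level (default 48).
#' @param eggs_lambda Mean egg count per fly (default 20; counts are
#'   1 + Poisson(lambda - 1)).
#' @param wall_prob,drop_prob Per-egg wall/drop probabilities.
#' @param seed Integer seed.
#' @return List with `records` (egg-record data frame) and `ground_truth`
#'   (the generating parameters).
#' @export
simulate_egg_depths <- function(firmness = c(0.75, 1, 1.25, 1.5, 1.75,
                                             2, 2.25, 2.5),
                                mean_depth = c(0.95, 0.9, 0.8, 0.65,
                                               0.45, 0.3, 0.2, 0.15),
                                n_flies = 48, eggs_lambda = 20,
                                wall_prob = 0.02, drop_prob = 0.02,
                                seed = 1) {
  stopifnot(length(mean_depth) == length(firmness),
            all(mean_depth >= 0 & mean_depth <= 1))
  with_seed(seed, {
    recs <- NULL
    for (i in seq_along(firmness)) {
      for (f in seq_len(n_flies)) {
        k <- 1L + stats::rpois(1, eggs_lambda - 1)
        depth <- stats::rbinom(k, 2, mean_depth[i]) / 2
        recs <- rbind(recs, data.frame(
          fly_id = sprintf("s%g_fly%02d", firmness[i], f),
          depth = depth,
          location = ifelse(stats::runif(k) < wall_prob, "wall",
                            "substrate"),
          mode = ifelse(stats::runif(k) < drop_prob, "dropped",
                        "burrowed"),
          substrate_pct = firmness[i]))
      }
    }
    if (is.null(recs))
      recs <- data.frame(fly_id = character(0), depth = numeric(0),
                         location = character(0), mode = character(0),
                         substrate_pct = numeric(0))
    list(records = recs,
         ground_truth = list(firmness = firmness, mean_depth = mean_depth,
                             wall_prob = wall_prob, drop_prob = drop_prob))
  })
}

#' Simulate a feature matrix of temporally blocked behavioral motifs
#'
#' Generates a frames x 17 feature matrix in which time is divided into
#' bouts, each expressing one of `n_motifs` motifs; a motif is a Gaussian
#' cloud around a motif-specific mean in feature space. Separation is the
#' distance between motif means in units of the within-motif standard
#' deviation. Used as the ground-truthed benchmark for the embedding and
#' density-segmentation stages.
#'
#' @param n_motifs Number of motifs (e.g. 2 or 5).
#' @param n_bouts Number of bouts (motif blocks) in the recording.
#' @param bout_len Frames per bout (default 50).
#' @param separation Mean separation in noise-sd units (default 8).
#' @param fps Frame rate carried in the attribute (default 20).
#' @param seed Integer seed.
#' @return List with `features` (matrix with the 17 standard column
#'   names), `motif` (integer per frame) and `means`.
#' @export
simulate_motif_features <- function(n_motifs = 2, n_bouts = 60,
                                    bout_len = 50, separation = 8,
                                    fps = 20, seed = 1) {
  with_seed(seed, {
    mu <- matrix(stats::rnorm(n_motifs * 17), n_motifs, 17)
    mu <- mu / sqrt(rowSums(mu^2)) * separation / sqrt(2)
    motif_of_bout <- rep_len(seq_len(n_motifs), n_bouts)[
      sample.int(n_bouts)]
    motif <- rep(motif_of_bout, each = bout_len)
    n <- length(motif)
    X <- mu[motif, , drop = FALSE] + matrix(stats::rnorm(n * 17), n, 17)
    colnames(X) <- feature_names()
    attr(X, "fps") <- fps
    list(features = X, motif = motif, means = mu)
  })
}
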