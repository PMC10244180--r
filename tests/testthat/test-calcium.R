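test_that("dF/F0 baselines follow the exclusion rules", {
  rec <- fluorescence_recording(rep(100, 600), fps = 10)
  d <- compute_dff(rec)
  expect_true(all(d$dff == 0))

  # baseline 100, plateau 150 after egg_out-20s -> plateau dFF = 0.5
  f <- rep(100, 600); f[401:600] <- 150
  rec2 <- fluorescence_recording(f, fps = 10)
  d2 <- compute_dff(rec2, egg_out_time = 60)
  expect_equal(unname(d2$f0), 100)
  expect_equal(unname(d2$dff[500, 1]), 0.5)

  # a transient inside an extrusion exclusion window leaves F0 untouched
  f3 <- rep(100, 600); f3[295:315] <- 500
  rec3 <- fluorescence_recording(f3, fps = 10)
  d3 <- compute_dff(rec3, extrusion_events = 30, exclude_s = 20)
  expect_equal(unname(d3$f0), 100)

  # multiplying F by a positive constant leaves dF/F0 identical
  d4 <- compute_dff(fluorescence_recording(3.7 * f, fps = 10),
                    egg_out_time = 60)
  expect_equal(d4$dff, d2$dff)

  expect_error(compute_dff(rec, egg_out_time = 10, exclude_s = 20),
               "empty baseline")
})

test_that("distance normalization sets the T6-analia unit to 1", {
  nd <- normalize_distances(list(t6_egg = rep(100, 50)), rep(50, 50))
  expect_equal(unique(nd$t6_egg), 2)
  expect_equal(nd$norm_constant, 50)
  # the reference trace itself normalizes to median 1
  self <- normalize_distances(list(x = rep(50, 50)), rep(50, 50))
  expect_equal(median(self$x), 1)
  # scaling all inputs leaves outputs unchanged
  nd2 <- normalize_distances(list(t6_egg = rep(300, 50)), rep(150, 50))
  expect_equal(nd2$t6_egg, nd$t6_egg)
  expect_error(normalize_distances(list(x = 1:5), rep(0, 5)), "positive")
})

test_that("the TV denoiser is exact: KKT certificate and step structure", {
  set.seed(11)
  # optimality certificate: the dual running sum stays within [-l, l]
  # and closes at 0; at interior jumps it sits on the correct bound
  for (i in 1:20) {
    n <- sample(20:150, 1)
    y <- rnorm(n) + cumsum(sample(c(0, 0, 1), n, replace = TRUE))
    lam <- runif(1, 0.05, 2)
    x <- tv_denoise(y, lam)
    s <- cumsum(x - y)
    expect_true(all(abs(s[-n]) <= lam + 1e-8))
    expect_lt(abs(s[n]), 1e-8)
    j <- which(abs(diff(x)) > 1e-10)
    if (length(j)) {
      expect_true(all(abs(abs(s[j]) - lam) < 1e-8))
      expect_true(all(sign(s[j]) == sign(diff(x)[j])))
    }
  }
  # noiseless piecewise-constant input: at most K+1 distinct levels
  y2 <- rep(c(0, 4, 1, 6), each = 30)
  x2 <- tv_denoise(y2, 0.5)
  expect_lte(length(unique(round(x2, 9))), 4)
  expect_identical(tv_denoise(y2, 0), y2)
  # huge lambda: everything shrinks to the mean
  expect_equal(unique(round(tv_denoise(y2, 1e6), 9)),
               round(mean(y2), 9))
})

test_that("event detection hits steps at one-fifth of the regularized max", {
  sim <- simulate_fluorescence(onsets = c(30, 60, 90, 120, 150),
                               types = "incomplete_expulsion",
                               duration_s = 180, seed = 2, step_px = 15,
                               dist_noise_sd = 3)
  nd <- normalize_distances(sim$distances["t6_egg"],
                            sim$distances$t6_analia)
  ev <- detect_events(nd$t6_egg, fps = 10)
  expect_equal(nrow(ev), 5)
  expect_true(all(abs(ev$onset_frame - c(30, 60, 90, 120, 150) * 10) <= 2))
  expect_equal(attr(ev, "threshold"),
               0.2 * max(attr(ev, "regularized")))

  # flat trace plus white noise: no events, with a warning
  set.seed(3)
  nd2 <- normalize_distances(list(x = 20 + rnorm(1500, 0, 0.5)),
                             rep(50, 1500))
  expect_warning(ev2 <- detect_events(nd2$x, fps = 10), "noise")
  expect_equal(nrow(ev2), 0)
})

test_that("3-s integrals and context anchors normalize as designed", {
  fps <- 10
  # all-zero trace: raw and normalized integrals are 0
  z <- structure(list(dff = matrix(0, 1500, 1), f0 = 100, fps = fps),
                 class = "dff_trace")
  iz <- integrate_and_normalize(z, events = c(20, 40),
                                design = "expulsion_context",
                                egg_out_time = 120)
  expect_true(all(iz$raw == 0) && all(iz$normalized == 0))

  # rectangular response of height 1 over exactly [0, 3] s -> integral 3
  v <- numeric(1500); v[801:831] <- 1   # frames 800..830 = t 80..83 s
  r <- structure(list(dff = matrix(v, ncol = 1), f0 = 100, fps = fps),
                 class = "dff_trace")
  ir <- integrate_and_normalize(r, events = 80,
                                design = "expulsion_context",
                                egg_out_time = 120,
                                exclusion_events = 80)
  expect_equal(ir$raw[1, 1], 3, tolerance = 1e-6)
  # the anchors themselves map to exactly 0 and 1
  expect_equal(unname((ir$anchor0 - ir$anchor0) /
                        (ir$anchor1 - ir$anchor0)), 0)
  expect_equal(ir$normalized[1, 1],
               (3 - ir$anchor0) / (ir$anchor1 - ir$anchor0))
  expect_equal(unname(ir$anchor1), 3, tolerance = 1e-6)
  expect_equal(unname(ir$anchor0), 0)
  expect_equal(ir$normalized[1, 1], 1, tolerance = 1e-6)

  # responsive vs non-responsive events separate at 5x noise
  sim <- simulate_fluorescence(onsets = c(100, 140, 170),
                               types = "incomplete_expulsion",
                               duration_s = 200, amplitude = 1,
                               noise_sd = 2, seed = 6)
  d <- compute_dff(sim$recording)
  ii <- integrate_and_normalize(d, events = c(100, 140, 170),
                                design = "expulsion_context",
                                egg_out_time = 190,
                                exclusion_events = c(100, 140, 170))
  quiet <- integrate_and_normalize(d, events = c(20, 30, 45),
                                   design = "expulsion_context",
                                   egg_out_time = 190,
                                   exclusion_events = c(100, 140, 170))
  expect_gt(min(ii$normalized), max(quiet$normalized))
})

test_that("event-triggered averages align and pool correctly", {
  fps <- 10
  # single trace, single event: mean equals the snippet, sem 0
  v <- numeric(400); v[201:220] <- 2
  d <- structure(list(dff = matrix(v, ncol = 1), f0 = 1, fps = fps),
                 class = "dff_trace")
  eta <- event_triggered_average(d, events = 20, window_s = c(-1, 1))
  expect_equal(as.vector(eta$mean), v[191:211])
  expect_true(all(eta$sem == 0))

  # two snippets {0-trace, 2-trace} -> mean 1 everywhere
  d2 <- structure(list(dff = cbind(rep(0, 400), rep(2, 400)), f0 = c(1, 1),
                       fps = fps), class = "dff_trace")
  eta2 <- event_triggered_average(d2, events = 20, window_s = c(-1, 1))
  expect_true(all(eta2$mean == 1))

  # simulated transients: pooled mean argmax at the kernel peak time
  tr <- 0.4; td <- 2.2
  tpk <- tr * td / (td - tr) * log(td / tr)
  sim <- simulate_fluorescence(onsets = c(50, 100, 150), tau_rise = tr,
                               tau_decay = td, duration_s = 200,
                               noise_sd = 0.5, seed = 8)
  d3 <- compute_dff(sim$recording)
  eta3 <- event_triggered_average(d3, events = c(50, 100, 150),
                                  window_s = c(-5, 10))
  expect_lte(abs(eta3$time_s[which.max(eta3$mean)] - tpk), 0.2 + 1e-9)
  expect_error(event_triggered_average(d3, numeric(0)), "no events")
})
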