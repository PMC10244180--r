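test_that("keypoint CSV reader handles the three-header dialect and gaps", {
  d <- tempfile(); dir.create(d)
  p <- file.path(d, "kp.csv")
  writeLines(c(
    "scorer,m,m,m,m,m,m",
    "bodyparts,scutellum,scutellum,scutellum,ocellus,ocellus,ocellus",
    "coords,x,y,likelihood,x,y,likelihood",
    "0,0,0,1,5,5,1",
    "1,1,1,1,5,5,1",
    "2,9,9,0.1,5,5,1",   # low confidence: interpolated
    "3,3,3,1,5,5,1",
    "4,4,4,1,5,5,1"), p)
  tr <- read_keypoints(p, px_per_mm = 10, fps = 20, min_confidence = 0.9)
  expect_equal(dim(tr$xy)[1], 5)
  expect_equal(unname(tr$xy[3, "scutellum", ]), c(2, 2))  # midpoint
  expect_equal(nrow(tr$interpolated$scutellum), 1)
  expect_equal(unname(tr$confidence[3, "scutellum"]), 0.1)  # raw kept

  writeLines(c("scorer,m", "bodyparts,scutellum", "coords,z", "0,1"), p)
  expect_error(read_keypoints(p, 10), "x/y/likelihood")
})

test_that("keypoint writer round trips through the reader", {
  tr <- make_track(25)
  set.seed(1)
  tr$xy <- tr$xy + rnorm(length(tr$xy))
  p <- tempfile(fileext = ".csv")
  write_keypoints(tr, p)
  tr2 <- read_keypoints(p, px_per_mm = tr$px_per_mm, fps = tr$fps)
  expect_equal(tr2$xy, tr$xy, tolerance = 1e-12)
  expect_equal(tr2$confidence, tr$confidence)
})

test_that("kinematic channels behave on constructed motions", {
  # perfectly stationary: all movement channels zero, ba constant
  tr <- make_track(40)
  k <- kinematic_features(tr)
  expect_true(all(k$vel == 0))
  expect_true(all(k$pe == 0))
  expect_true(all(k$T1 == 0) && all(k$T3 == 0) && all(k$A5_move == 0))
  expect_equal(length(unique(round(k$ba_raw, 12))), 1)

  # scutellum at 2 px/frame, fps 20, lag 10 -> 20 px over 0.5 s = 40 px/s
  tr2 <- make_track(40)
  tr2$xy[, "scutellum", 1] <- 2 * (0:39)
  k2 <- kinematic_features(tr2, speed_lag_frames = 10)
  expect_equal(unname(k2$vel[20]), 40)

  # vel is invariant under a global translation of all keypoints
  tr3 <- make_track(40, drift = 7.5)
  tr3$xy[, "scutellum", 1] <- tr3$xy[, "scutellum", 1] + 2 * (0:39)
  k3 <- kinematic_features(tr3)
  expect_equal(k3$vel, k2$vel, tolerance = 1e-12)

  # ba is invariant under a global rotation of the whole frame
  trR <- make_track(40)
  th0 <- 0.7
  R <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2)
  for (p in dimnames(trR$xy)[[2]])
    trR$xy[, p, ] <- trR$xy[, p, , drop = TRUE] %*% t(R)
  expect_equal(kinematic_features(trR)$ba_raw, k$ba_raw,
               tolerance = 1e-9)

  # monotone abdomen rotation: velba one-signed before z-scoring
  tr4 <- make_track(60)
  th <- seq(0, 0.5, length.out = 60)
  r0 <- tr4$xy[1, "stripe_A6", ] - tr4$xy[1, "stripe_A2", ]
  tr4$xy[, "stripe_A6", 1] <- tr4$xy[, "stripe_A2", 1] +
    r0[1] * cos(th) - r0[2] * sin(th)
  tr4$xy[, "stripe_A6", 2] <- tr4$xy[, "stripe_A2", 2] +
    r0[1] * sin(th) + r0[2] * cos(th)
  k4 <- kinematic_features(tr4)
  expect_true(all(diff(k4$ba_raw) > 0) || all(diff(k4$ba_raw) < 0))

  # z-scored channels: mean ~ 0, sd ~ 1
  expect_lt(abs(mean(k4$ba)), 1e-8)
  expect_lt(abs(sd(k4$ba) - 1), 1e-8)
  expect_error(kinematic_features(make_track(5), speed_lag_frames = 10),
               "lag")
})

test_that("walking classifier matches the paper threshold and a naive oracle", {
  fps <- 20
  expect_true(all(walking_bouts(rep(0.30, 100), fps)$walk))
  expect_false(any(walking_bouts(rep(0.28, 100), fps)$walk))

  # step 0 -> 1 mm/s: onset within half the smoothing window of the step
  v <- c(rep(0, 100), rep(1, 100))
  wb <- walking_bouts(v, fps)
  onset <- which(wb$walk)[1] - 1L  # 0-based
  expect_lte(abs(onset - 100), 0.5 * fps)

  # exact agreement with the brute-force sliding window on random input
  set.seed(31)
  for (i in 1:50) {
    v <- pmax(0, rnorm(120, 0.29, 0.2))
    expect_identical(walking_bouts(v, fps)$walk, naive_walking(v, fps))
  }
  expect_error(walking_bouts(v, fps, smooth_s = 0), "positive")
})

test_that("Morlet band magnitudes are frequency selective", {
  # ovi bands at the video rate; tones at the geometric band centers
  fps <- 20
  t <- seq(0, 60, by = 1 / fps)
  bands <- list(c(0.8, 1.3), c(1.3, 2.3))
  interior <- 400:800
  for (i in 1:2) {
    f0 <- sqrt(prod(bands[[i]]))
    m <- morlet_band_features(sin(2 * pi * f0 * t), fps, bands)
    expect_true(all(apply(m[interior, ], 1, which.max) == i),
                info = paste("band", i))
  }
  # the 7 log-spaced A5 bands, sampled fast enough to represent 10 Hz
  fps2 <- 64
  t2 <- seq(0, 60, by = 1 / fps2)
  cf <- cwt_center_frequencies()
  bl <- lapply(cf, function(f) c(f, f))
  for (i in seq_along(cf)) {
    m <- morlet_band_features(sin(2 * pi * cf[i] * t2), fps2, bl,
                              n_per_band = 1)
    expect_true(all(apply(m[1500:2500, ], 1, which.max) == i),
                info = paste("cwt band", i))
  }
  # constant signal: zero magnitude, log output at the floor
  flat <- morlet_band_features(rep(2, 500), fps, bands)
  expect_lt(max(flat), 1e-10)
  flatlog <- morlet_band_features(rep(2, 500), fps, bands,
                                  log_output = TRUE, eps = 1e-6)
  expect_equal(unique(as.vector(flatlog)), log(1e-6))
  expect_error(morlet_band_features(t, 10, list(c(4, 6))), "Nyquist")
})

test_that("the assembled feature matrix has the 17 canonical columns", {
  sim <- simulate_ethogram(n_events = 1, seed = 6)
  e <- sim$ethograms[[1]]
  kp <- simulate_keypoints(e, seed = 2)
  fm <- build_feature_matrix(kp$track, kp$ovi_intensity)
  expect_equal(ncol(fm), 17)
  expect_equal(colnames(fm),
               c("vel", "pe", "ba", "velba", "T1", "T2", "T3", "Pegg",
                 "w1ovi", "w2ovi", paste0("cwt", 1:7)))
  expect_false(anyNA(fm))
  expect_false(attr(fm, "ovi_fallback"))
  # fallback flagged when no intensity trace is given
  fm2 <- build_feature_matrix(kp$track)
  expect_true(attr(fm2, "ovi_fallback"))

  # stationary track + constant intensity: movement channels all zero,
  # wavelet channels at zero / the log floor
  tr <- make_track(200)
  fm3 <- build_feature_matrix(tr, rep(50, 200))
  expect_true(all(fm3[, c("vel", "pe", "T1", "T2", "T3")] == 0))
  expect_lt(max(fm3[, c("w1ovi", "w2ovi")]), 1e-10)
  expect_equal(unique(as.vector(fm3[, paste0("cwt", 1:7)])), log(1e-6))
})

test_that("burrowing drives the matching ovipositor wavelet band", {
  e <- make_ethogram(list(walk = list(c(0, 200)),
                          burrow = list(c(300, 700)),
                          bend = list(c(280, 720))), 1000)
  for (cfg in list(list(f = 1.0, col = "w1ovi", other = "w2ovi"),
                   list(f = 1.5, col = "w2ovi", other = "w1ovi"))) {
    kp <- simulate_keypoints(e, burrow_freq_start = cfg$f,
                             burrow_freq_end = cfg$f, seed = 4)
    fm <- build_feature_matrix(kp$track, kp$ovi_intensity)
    epoch <- 350:650
    rest <- 1:200
    expect_gt(mean(fm[epoch, cfg$col]), mean(fm[rest, cfg$col]))
    expect_gt(mean(fm[epoch, cfg$col]), mean(fm[epoch, cfg$other]))
  }
})
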