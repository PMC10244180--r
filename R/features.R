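feature_names <- function() {
  c("vel", "pe", "ba", "velba", "T1", "T2", "T3", "Pegg",
    "w1ovi", "w2ovi", paste0("cwt", 1:7))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# centered moving average with shrinking (partial) windows at the edges
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

frame_displacement <- function(p) {
  # per-frame Euclidean displacement (px/frame); first frame 0
  d <- sqrt(rowSums(diff(p)^2))
  c(0, d)
}

#' Kinematic channels from a keypoint track
#'
#' Computes the per-frame kinematic features feeding the 17-column feature
#' matrix: `vel`, the scutellum speed measured as the distance between the
#' scutellum position `speed_lag_frames` apart divided by the lag (px/s;
#' the first lag frames hold the first computable value); `pe`, the
#' per-frame displacement of the proboscis tip relative to the ocellus;
#' `T1`-`T3`, per-frame leg-joint displacements; `A5_move`, per-frame
#' displacement of the A5 stripe; `ba`, the per-recording z-score of the
#' signed angle between the abdominal line (stripe A2 -> stripe A6) and the
#' body axis (ocellus -> scutellum); `velba`, the per-frame difference of
#' the unnormalized angle, z-scored; and `Pegg`, the egg-tip tracking
#' confidence passed through unchanged.
#'
#' @param track A `keypoint_track`.
#' @param speed_lag_frames Lag for the speed estimate (default 10, i.e.
#'   500 ms at 20 fps).
#' @return List of named numeric channels, plus `ba_raw` (the unnormalized
#'   angle, radians).
#' @export
kinematic_features <- function(track, speed_lag_frames = 10) {
  xy <- track$xy
  n <- dim(xy)[1]
  if (n <= speed_lag_frames) stop("track shorter than the speed lag")
  need <- c("scutellum", "ocellus", "proboscis_tip", "stripe_A2",
            "stripe_A5", "stripe_A6", "leg_T1", "leg_T2", "leg_T3",
            "egg_tip")
  miss <- setdiff(need, dimnames(xy)[[2]])
  if (length(miss)) stop("missing bodypart(s): ", paste(miss, collapse = ", "))
  P <- function(p) xy[, p, , drop = TRUE]
  lag <- speed_lag_frames
  sc <- P("scutellum")
  d <- sqrt(rowSums((sc[-seq_len(lag), , drop = FALSE] -
                     sc[seq_len(n - lag), , drop = FALSE])^2))
  vel <- c(rep(d[1], lag), d) / (lag / track$fps)
  pe <- frame_displacement(P("proboscis_tip") - P("ocellus"))
  ab <- P("stripe_A6") - P("stripe_A2")
  ax <- P("scutellum") - P("ocellus")
  ang <- atan2(ab[, 1] * ax[, 2] - ab[, 2] * ax[, 1],
               rowSums(ab * ax))
  dang <- diff(ang)
  dang <- c(if (length(dang)) dang[1] else 0, dang)
  list(vel = vel,
       pe = pe,
       ba = zscore(ang),
       ba_raw = ang,
       velba = zscore(dang),
       T1 = frame_displacement(P("leg_T1")),
       T2 = frame_displacement(P("leg_T2")),
       T3 = frame_displacement(P("leg_T3")),
       A5_move = frame_displacement(P("stripe_A5")),
       Pegg = track$confidence[, "egg_tip"])
}

#' Threshold walking classifier
#'
#' A fly is classified as walking on frames where its speed, smoothed by a
#' centered moving average of `smooth_s` seconds, exceeds `threshold`
#' (default 0.29 mm/s). Edge frames use shrinking windows.
#'
#' @param vel Speed channel in mm/s.
#' @param fps Frame rate.
#' @param threshold Walking threshold in mm/s (default 0.29).
#' @param smooth_s Smoothing window in seconds (default 1).
#' @return List with `walk` (logical per frame), `smoothed` (mm/s) and
#'   `bouts` (data frame `start`, `end`, `duration_s`; 0-based half-open).
#' @export
walking_bouts <- function(vel, fps, threshold = 0.29, smooth_s = 1.0) {
  if (smooth_s <= 0) stop("smoothing window must be positive")
  w <- max(1L, round(smooth_s * fps))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- moving_average(vel, w)
  walk <- sm > threshold
  r <- rle(walk)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  list(walk = walk, smoothed = sm,
       bouts = data.frame(start = starts[keep], end = ends[keep],
                          duration_s = r$lengths[keep] / fps))
}

#' Continuous Morlet wavelet magnitude
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (center-frequency parameter `omega0` cycles, default 6).
#' Magnitudes are amplitude-normalized: a unit sinusoid at a requested
#' frequency yields magnitude ~ 1 at that frequency away from the edges. A
#' constant signal transforms to exactly zero (the analytic wavelet has no
#' DC response).
#'
#' @param x Numeric time series.
#' @param fps Sampling rate (Hz).
#' @param freqs Center frequencies (Hz), all below Nyquist.
#' @param omega0 Morlet center-frequency parameter (default 6).
#' @return Matrix `length(x)` x `length(freqs)` of magnitudes.
#' @export
morlet_magnitude <- function(x, fps, freqs, omega0 = 6) {
  if (any(freqs > fps / 2)) stop("frequency above Nyquist")
  n <- length(x)
  xf <- stats::fft(x)
  k <- seq_len(n) - 1L
  wk <- ifelse(k <= n / 2, k, k - n) * (2 * pi * fps / n)  # angular freq
  out <- matrix(0, n, length(freqs))
  for (j in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[j])
    H <- ifelse(wk > 0, 2 * exp(-(s * wk - omega0)^2 / 2), 0)
    out[, j] <- Mod(stats::fft(xf * H, inverse = TRUE)) / n
  }
  colnames(out) <- sprintf("f%.3g", freqs)
  out
}

#' Band-averaged Morlet wavelet features
#'
#' For each `(low, high)` band, averages the Morlet magnitude over
#' `n_per_band` log-spaced center frequencies within the band, yielding one
#' channel per band. With `log_output`, returns the natural log of the
#' magnitude floored at `eps`.
#'
#' @param x Numeric time series.
#' @param fps Sampling rate (Hz); must exceed twice the highest band edge.
#' @param bands List of `c(low, high)` Hz pairs.
#' @param log_output Return log magnitudes (default `FALSE`).
#' @param n_per_band Frequencies sampled per band (default 5).
#' @param eps Log floor (default 1e-6).
#' @param omega0 Morlet parameter (default 6).
#' @return Matrix `length(x)` x `length(bands)`.
#' @export
morlet_band_features <- function(x, fps, bands, log_output = FALSE,
                                 n_per_band = 5, eps = 1e-6, omega0 = 6) {
  hi <- max(vapply(bands, max, numeric(1)))
  if (fps < 2 * hi) stop("band edge above Nyquist")
  out <- vapply(bands, function(b) {
    fr <- exp(seq(log(b[1]), log(b[2]), length.out = n_per_band))
    fr <- pmin(pmax(fr, b[1]), b[2])  # guard fp round-off at the edges
    rowMeans(morlet_magnitude(x, fps, fr, omega0))
  }, numeric(length(x)))
  if (log_output) out <- log(pmax(out, eps))
  out
}

#' The seven log-spaced wavelet center frequencies (0.5-10 Hz)
#' @return Numeric vector of length 7.
#' @export
cwt_center_frequencies <- function() {
  f <- exp(seq(log(0.5), log(10), length.out = 7))
  f[c(1, 7)] <- c(0.5, 10)  # pin endpoints against fp round-off
  f
}

#' Assemble the 17-column frame-wise feature matrix
#'
#' Columns, in fixed order: `vel`, `pe`, `ba`, `velba`, `T1`, `T2`, `T3`,
#' `Pegg`, `w1ovi`, `w2ovi`, `cwt1`..`cwt7`. The two `w` channels are the
#' linear Morlet band magnitudes (0.8-1.3 and 1.3-2.3 Hz) of the ovipositor
#' ROI mean-intensity trace; when no intensity trace is supplied, the
#' per-frame displacement of the ovipositor keypoint is used instead and
#' the result is flagged (`attr(fm, "ovi_fallback")`). `cwt1`..`cwt7` are
#' log magnitudes of the A5-stripe movement at seven log-spaced center
#' frequencies from 0.5 to 10 Hz. The assembled matrix contains no NaN.
#'
#' @param track A `keypoint_track` containing all required bodyparts.
#' @param ovi_intensity Optional ovipositor-ROI mean-intensity trace, one
#'   value per frame.
#' @param speed_lag_frames Lag for the speed channel (default 10).
#' @return Numeric matrix frames x 17 with attribute `fps`.
#' @export
build_feature_matrix <- function(track, ovi_intensity = NULL,
                                 speed_lag_frames = 10) {
  kin <- kinematic_features(track, speed_lag_frames)
  n <- length(kin$vel)
  fallback <- is.null(ovi_intensity)
  if (fallback) {
    if (!"ovipositor" %in% dimnames(track$xy)[[2]])
      stop("missing bodypart(s): ovipositor")
    ovi_intensity <- frame_displacement(track$xy[, "ovipositor", ,
                                                 drop = TRUE])
  }
  if (length(ovi_intensity) != n)
    stop("ovi_intensity length must match the track")
  w <- morlet_band_features(ovi_intensity, track$fps,
                            list(c(0.8, 1.3), c(1.3, 2.3)))
  cwt <- morlet_band_features(kin$A5_move, track$fps,
                              lapply(cwt_center_frequencies(),
                                     function(f) c(f, f)),
                              log_output = TRUE, n_per_band = 1)
  fm <- cbind(vel = kin$vel, pe = kin$pe, ba = kin$ba, velba = kin$velba,
              T1 = kin$T1, T2 = kin$T2, T3 = kin$T3, Pegg = kin$Pegg,
              w1ovi = w[, 1], w2ovi = w[, 2], cwt)
  colnames(fm) <- feature_names()
  stopifnot(!anyNA(fm))
  attr(fm, "fps") <- track$fps
  attr(fm, "ovi_fallback") <- fallback
  fm
}
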