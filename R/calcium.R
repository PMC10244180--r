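#' Construct a two-channel fluorescence recording
#'
#' @param green Raw activity-channel fluorescence: frames x ROI matrix (a
#'   vector is treated as one ROI). Values must be non-negative.
#' @param red Optional anatomical-channel trace(s), same shape.
#' @param fps Acquisition rate (default 10 Hz).
#' @param roi_ids ROI names (default `roi1`, `roi2`, ...).
#' @return A `fluorescence_recording`.
#' @export
fluorescence_recording <- function(green, red = NULL, fps = 10,
                                   roi_ids = NULL) {
  green <- as.matrix(green)
  if (any(green < 0)) stop("fluorescence must be non-negative")
  if (!is.null(red)) {
    red <- as.matrix(red)
    if (!all(dim(red) == dim(green))) stop("red/green shape mismatch")
  }
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(ncol(green)))
  colnames(green) <- roi_ids
  structure(list(green = green, red = red, fps = fps, roi_ids = roi_ids),
            class = "fluorescence_recording")
}

#' Convert raw fluorescence to dF/F0
#'
#' The baseline F0 for each ROI is the median fluorescence from recording
#' onset up to `exclude_s` seconds before completed egg expulsion,
#' excluding the union of +-`exclude_s` windows around ovipositor extrusion
#' events. Without an `egg_out_time`, the baseline window is the full trace
#' minus the exclusions. Analysis traces are returned unsmoothed; use
#' [smooth_dff()] for 3-point display smoothing.
#'
#' @param rec A `fluorescence_recording`.
#' @param egg_out_time Optional completed-expulsion time (s).
#' @param extrusion_events Ovipositor extrusion onsets (s) to exclude.
#' @param exclude_s Exclusion half-window (default 20 s).
#' @return A `dff_trace`: list with `dff` (frames x ROI), `f0` (per ROI),
#'   `fps` and `provenance` (baseline frame count and windows).
#' @export
compute_dff <- function(rec, egg_out_time = NULL,
                        extrusion_events = numeric(0), exclude_s = 20) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  n <- nrow(rec$green)
  t <- (seq_len(n) - 1L) / rec$fps
  ok <- rep(TRUE, n)
  if (!is.null(egg_out_time)) ok <- t <= egg_out_time - exclude_s
  for (ev in extrusion_events) ok <- ok & abs(t - ev) > exclude_s
  if (!any(ok)) stop("empty baseline window after exclusions")
  f0 <- apply(rec$green[ok, , drop = FALSE], 2, stats::median)
  if (any(f0 <= 0)) stop("non-positive baseline F0")
  dff <- sweep(sweep(rec$green, 2, f0), 2, f0, "/")
  structure(list(dff = dff, f0 = f0, fps = rec$fps,
                 provenance = list(n_baseline_frames = sum(ok),
                                   egg_out_time = egg_out_time,
                                   extrusion_events = extrusion_events,
                                   exclude_s = exclude_s)),
            class = "dff_trace")
}

#' Three-point moving-average display smoothing
#'
#' @param dff A `dff_trace` (or numeric matrix/vector).
#' @param k Window length (default 3).
#' @return The smoothed dF/F0 values (same shape as the input traces).
#' @export
smooth_dff <- function(dff, k = 3) {
  x <- if (inherits(dff, "dff_trace")) dff$dff else as.matrix(dff)
  apply(x, 2, moving_average, w = k)
}

#' Normalize tracked distances to the T6-analia unit
#'
#' Divides each raw pixel-distance trace by the median distance between T6
#' and the posterior edge of the analia base, which is thereby set to 1.
#'
#' @param raw Named list (or data frame) of raw distance traces in px,
#'   e.g. `t6_egg`, `t6_ovi`, `ovi_egg`.
#' @param t6_analia Raw T6-analia distance trace in px (positive median).
#' @return List with the normalized traces and `norm_constant` (px).
#' @export
normalize_distances <- function(raw, t6_analia) {
  m <- stats::median(t6_analia)
  if (!is.finite(m) || m <= 0) stop("T6-analia median must be positive")
  out <- lapply(raw, function(x) x / m)
  out$norm_constant <- m
  out
}

#' Zero-phase first-order high-pass filter
#'
#' Butterworth design applied forward and backward (zero phase lag).
#'
#' @param x Numeric trace.
#' @param fps Sampling rate (Hz).
#' @param cutoff Cutoff frequency in Hz (default 0.001).
#' @return Filtered trace.
#' @export
highpass_filter <- function(x, fps, cutoff = 0.001) {
  bf <- signal::butter(1, cutoff / (fps / 2), type = "high")
  # remove the DC component first: at cutoff periods much longer than the
  # trace the forward-backward edge transient would otherwise leak a
  # mean-proportional ramp into the output
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Exact 1-D total-variation denoising
#'
#' Solves min_x 0.5 * sum((x - y)^2) + lambda * sum(|x_{i+1} - x_i|)
#' exactly with a direct O(n) taut-string sweep, producing the
#' piecewise-constant signal used to stabilize threshold-crossing event
#' detection.
#'
#' @param y Numeric input trace.
#' @param lambda Non-negative regularization weight; 0 returns `y`.
#' @return The denoised trace.
#' @export
tv_denoise <- function(y, lambda) {
  n <- length(y)
  if (lambda < 0) stop("lambda must be non-negative")
  if (lambda == 0 || n <= 1L) return(y)
  x <- numeric(n)
  k <- 1L; k0 <- 1L; km <- 1L; kp <- 1L
  vmin <- y[1] - lambda; vmax <- y[1] + lambda
  umin <- lambda; umax <- -lambda
  repeat {
    if (k == n) {
      if (umin < 0) {
        x[k0:km] <- vmin; km <- km + 1L; k <- km; k0 <- km
        vmin <- y[k]; umin <- lambda; umax <- y[k] + lambda - vmax
      } else if (umax > 0) {
        x[k0:kp] <- vmax; kp <- kp + 1L; k <- kp; k0 <- kp
        vmax <- y[k]; umax <- -lambda; umin <- y[k] - lambda - vmin
      } else {
        x[k0:n] <- vmin + umin / (k - k0 + 1)
        return(x)
      }
      next
    }
    if (y[k + 1L] + umin < vmin - lambda) {
      x[k0:km] <- vmin
      km <- km + 1L; k <- km; k0 <- km; kp <- km
      vmin <- y[k]; vmax <- y[k] + 2 * lambda
      umin <- lambda; umax <- -lambda
    } else if (y[k + 1L] + umax > vmax + lambda) {
      x[k0:kp] <- vmax
      kp <- kp + 1L; k <- kp; k0 <- kp; km <- kp
      vmin <- y[k] - 2 * lambda; vmax <- y[k]
      umin <- lambda; umax <- -lambda
    } else {
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lambda) {
        vmin <- vmin + (umin - lambda) / (k - k0 + 1)
        umin <- lambda; km <- k
      }
      if (umax <= -lambda) {
        vmax <- vmax + (umax + lambda) / (k - k0 + 1)
        umax <- -lambda; kp <- k
      }
    }
  }
}

# pick lambda by the discrepancy principle: residual sd ~ noise estimate
# from the median absolute first difference
tv_lambda_discrepancy <- function(x, sigma, iters = 25) {
  if (sigma <= 0) return(0)
  lo <- 1e-8; hi <- max(abs(x - mean(x))) * length(x)
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    r <- stats::sd(x - tv_denoise(x, mid))
    if (r < 1.05 * sigma) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Detect behavioral events from a tracked-distance trace
#'
#' The trace is zero-phase high-pass filtered, denoised by exact 1-D total
#' variation regularization, and events are scored as upward crossings of
#' a threshold set at `frac` (default one-fifth) of the maximum of the
#' regularized signal. Crossings closer together than `refractory_s` are
#' merged (first onset kept). When the regularized signal never rises
#' meaningfully above the noise floor, no events are returned, with a
#' warning.
#'
#' @param trace Normalized distance trace.
#' @param fps Sampling rate (Hz).
#' @param hp_cutoff High-pass cutoff (default 0.001 Hz).
#' @param tv_lambda TV weight; `NULL` (default) selects it by the
#'   discrepancy principle against the median-absolute-difference noise
#'   estimate.
#' @param frac Threshold as a fraction of the regularized maximum
#'   (default 0.2).
#' @param refractory_s Merge window (default 1 s).
#' @param min_snr Minimum ratio of the regularized maximum to the noise sd
#'   below which no events are called (default 3).
#' @return Data frame with `onset_frame` (0-based) and `onset_s`, plus
#'   attributes `regularized` and `threshold`.
#' @export
detect_events <- function(trace, fps, hp_cutoff = 0.001, tv_lambda = NULL,
                          frac = 0.2, refractory_s = 1, min_snr = 3) {
  hp <- highpass_filter(trace, fps, hp_cutoff)
  # on traces short relative to the cutoff period the filter leaves a
  # residual offset; events are sparse, so the median is the baseline
  hp <- hp - stats::median(hp)
  sigma <- stats::mad(diff(hp)) / sqrt(2)
  if (is.null(tv_lambda)) tv_lambda <- tv_lambda_discrepancy(hp, sigma)
  reg <- tv_denoise(hp, tv_lambda)
  M <- max(reg)
  empty <- data.frame(onset_frame = integer(0), onset_s = numeric(0))
  if (M <= 0 || (sigma > 0 && M < min_snr * sigma)) {
    warning("regularized signal indistinguishable from noise: no events")
    attr(empty, "regularized") <- reg
    return(empty)
  }
  thr <- frac * M
  above <- reg >= thr
  cross <- which(diff(above) == 1L)  # 0-based frame of first point above
  if (above[1]) cross <- c(0L, cross)
  # snap each crossing to the dominant upward jump of the regularized
  # signal nearby: noise sub-steps can pre-cross the threshold by a few
  # frames, while the main jump marks the edge
  if (length(cross)) {
    d <- diff(reg)
    w <- max(1L, round(2 * refractory_s * fps))
    n <- length(reg)
    cross <- vapply(cross, function(cr) {
      cand <- max(1L, cr + 1L - w):min(n - 1L, cr + w)
      as.integer(cand[which.max(d[cand])])
    }, integer(1))
    cross <- sort(unique(cross))
  }
  if (length(cross) > 1L) {
    # greedy refractory merging
    last <- cross[1]; keep <- logical(length(cross)); keep[1] <- TRUE
    for (i in seq_along(cross)[-1]) {
      if (cross[i] - last >= refractory_s * fps) {
        keep[i] <- TRUE; last <- cross[i]
      }
    }
    cross <- cross[keep]
  }
  out <- data.frame(onset_frame = as.integer(cross), onset_s = cross / fps)
  attr(out, "regularized") <- reg
  attr(out, "threshold") <- thr
  out
}

#' Sliding fixed-width integral of a trace
#'
#' Trapezoidal integral of `x` over `[t, t + width_s]` at every frame step
#' `t` for which the full window fits.
#'
#' @param x Numeric trace.
#' @param fps Sampling rate (Hz).
#' @param width_s Window width (default 3 s).
#' @return List with `t` (window start times, s) and `integral`.
#' @export
sliding_integral <- function(x, fps, width_s = 3) {
  w <- round(width_s * fps)
  n <- length(x)
  if (n <= w) stop("trace shorter than the integration window")
  cs <- cumsum(x)
  i <- seq_len(n - w)
  ints <- (cs[i + w] - c(0, cs)[i] - 0.5 * (x[i] + x[i + w])) / fps
  list(t = (i - 1L) / fps, integral = ints)
}

#' Integrate event responses and normalize to context anchors
#'
#' For each event onset, the raw statistic is the trapezoidal integral of
#' dF/F0 over t = 0..3 s after onset. Raw integrals are then min-max
#' mapped per ROI so that a context-specific baseline anchor maps to 0 and
#' the maximum 3-s integral observed throughout maps to 1. In the
#' `expulsion_context` design the 0-anchor is the median sliding 3-s
#' integral over the first contiguous 60-s stretch before complete
#' expulsion that avoids +-20 s around any expulsion event, and a
#' post-expulsion value (median 3-s integral over t = 10..20 s after egg
#' out) is also reported. In the `extrusion_context` design the 0-anchor is
#' the median over the first 60 s worth of (possibly non-contiguous) valid
#' frames starting 10 s after egg out, excluding +-20 s around extrusion
#' events. Out-of-range normalized values are meaningful and are not
#' clipped. For ROIs with multiple events the per-ROI mean is also
#' returned.
#'
#' @param dff A `dff_trace`.
#' @param events Event onset times (s) to score.
#' @param design `"expulsion_context"` or `"extrusion_context"`.
#' @param egg_out_time Completed-expulsion time (s).
#' @param exclusion_events Onsets (s) excluded from the baseline anchor
#'   (expulsion events or extrusion events, per design); defaults to
#'   `events`.
#' @param exclude_s Exclusion half-window (default 20 s).
#' @param width_s Integration window (default 3 s).
#' @param baseline_span_s Anchor span (default 60 s).
#' @return List with `raw` and `normalized` (events x ROI matrices),
#'   `anchor0`, `anchor1`, `post_normalized` (expulsion design only) and
#'   `per_roi_mean`.
#' @export
integrate_and_normalize <- function(dff, events,
                                    design = c("expulsion_context",
                                               "extrusion_context"),
                                    egg_out_time,
                                    exclusion_events = events,
                                    exclude_s = 20, width_s = 3,
                                    baseline_span_s = 60) {
  design <- match.arg(design)
  stopifnot(inherits(dff, "dff_trace"))
  fps <- dff$fps
  n <- nrow(dff$dff)
  dur <- n / fps
  if (any(events < 0 | events + width_s > dur))
    stop("event window outside trace bounds")
  R <- ncol(dff$dff)
  sl <- lapply(seq_len(R), function(r)
    sliding_integral(dff$dff[, r], fps, width_s))
  tt <- sl[[1]]$t
  raw <- vapply(seq_len(R), function(r)
    stats::approx(sl[[r]]$t, sl[[r]]$integral, xout = events,
                  rule = 2)$y, numeric(length(events)))
  raw <- matrix(raw, nrow = length(events))
  valid <- rep(TRUE, length(tt))
  for (ev in exclusion_events) valid <- valid & abs(tt - ev) > exclude_s
  if (design == "expulsion_context") {
    valid <- valid & (tt <= egg_out_time)
    r <- rle(valid)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    need <- round(baseline_span_s * fps)
    run <- which(r$values & r$lengths >= need)
    if (length(run)) {
      sel <- seq.int(starts[run[1]], starts[run[1]] + need - 1L)
    } else {
      long <- which.max(r$lengths * r$values)
      if (!r$values[long]) stop("no valid baseline frames before egg out")
      warning("no contiguous ", baseline_span_s,
              " s baseline stretch; using the longest available")
      sel <- seq.int(starts[long], ends[long])
    }
  } else {
    cand <- which(valid & tt >= egg_out_time + 10)
    if (!length(cand)) stop("no valid baseline frames after egg out")
    sel <- cand[seq_len(min(length(cand), round(baseline_span_s * fps)))]
  }
  anchor0 <- vapply(sl, function(s) stats::median(s$integral[sel]),
                    numeric(1))
  anchor1 <- vapply(sl, function(s) max(s$integral), numeric(1))
  rng <- anchor1 - anchor0
  degen <- abs(rng) < 1e-12
  if (any(degen & colSums(abs(sweep(raw, 2, anchor0)) > 1e-12) > 0))
    stop("zero dynamic range: anchors coincide")
  rng[degen] <- 1  # all-zero traces: integrals equal the anchor, map to 0
  norm <- sweep(sweep(raw, 2, anchor0), 2, rng, "/")
  out <- list(raw = raw, normalized = norm, anchor0 = anchor0,
              anchor1 = anchor1,
              per_roi_mean = colMeans(norm))
  if (design == "expulsion_context") {
    post_sel <- which(tt >= egg_out_time + 10 & tt <= egg_out_time + 20)
    if (length(post_sel)) {
      post <- vapply(sl, function(s) stats::median(s$integral[post_sel]),
                     numeric(1))
      out$post_normalized <- (post - anchor0) / (anchor1 - anchor0)
    }
  }
  out
}

#' Event-triggered average of dF/F0 traces
#'
#' Aligns per-ROI dF/F0 snippets to event onsets, padding outside the
#' recording with NA, and pools the mean and standard error at each time
#' point ignoring missing values.
#'
#' @param dff A `dff_trace`.
#' @param events Event onset times (s).
#' @param window_s Two-element window around onset (default `c(-10, 20)`).
#' @return List with `time_s`, `snippets` ((ROI x event) x time matrix),
#'   `mean` and `sem`.
#' @export
event_triggered_average <- function(dff, events, window_s = c(-10, 20)) {
  if (!length(events)) stop("no events")
  fps <- dff$fps
  n <- nrow(dff$dff)
  rel <- seq.int(round(window_s[1] * fps), round(window_s[2] * fps))
  snippets <- NULL
  for (r in seq_len(ncol(dff$dff))) {
    for (ev in events) {
      fr <- round(ev * fps) + rel
      v <- rep(NA_real_, length(rel))
      ok <- fr >= 0L & fr < n
      v[ok] <- dff$dff[fr[ok] + 1L, r]
      snippets <- rbind(snippets, v)
    }
  }
  m <- colMeans(snippets, na.rm = TRUE)
  sem <- apply(snippets, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else 0
  })
  list(time_s = rel / fps, snippets = snippets, mean = m, sem = sem)
}
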