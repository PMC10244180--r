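# shared fixture builders for the test suite; everything is generated in
# code, nothing is read from disk unless a test writes it first

# ethogram from a compact bout spec: list(label = list(c(start, end), ...))
make_ethogram <- function(spec, n_frames, fps = 20, egg_out_frame = NULL,
                          cycle_frames = integer(0), location = NULL,
                          fly_id = "fly", event_id = "event") {
  a <- matrix(FALSE, n_frames, 7L,
              dimnames = list(NULL, behavior_labels()))
  for (lb in names(spec)) {
    for (rng in spec[[lb]]) a[(rng[1] + 1L):rng[2], lb] <- TRUE
  }
  ethogram(a, fps = fps, fly_id = fly_id, event_id = event_id,
           egg_out_frame = egg_out_frame, cycle_frames = cycle_frames,
           location = location)
}

# start_sequence straight from an item table (bypasses the extractor)
make_sequence <- function(labels, frames = seq_along(labels) * 10,
                          event_id = "e", fly_id = "f", fps = 20) {
  structure(list(event_id = event_id, fly_id = fly_id, fps = fps,
                 items = data.frame(label = labels, frame = frames),
                 phase_split = if (any(labels == "egg_out"))
                   which(labels == "egg_out")[1] else NA_integer_,
                 provenance = character(0)),
            class = "start_sequence")
}

# independent brute-force pair tally for transition counts
naive_transition_counts <- function(seq_list) {
  labs <- behavior_labels()
  cnt <- matrix(0L, 7, 7, dimnames = list(labs, labs))
  for (s in seq_list) {
    l <- s$items$label
    if (length(l) < 2) next
    for (i in seq_len(length(l) - 1))
      cnt[l[i], l[i + 1]] <- cnt[l[i], l[i + 1]] + 1L
  }
  cnt
}

# naive sliding-window walking classifier (frame loop)
naive_walking <- function(vel, fps, threshold = 0.29, smooth_s = 1.0) {
  w <- max(1L, round(smooth_s * fps))
  if (w %% 2L == 0L) w <- w + 1L
  h <- floor(w / 2)
  n <- length(vel)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    out[i] <- mean(vel[lo:hi]) > threshold
  }
  out
}

# naive frame-loop F1 between two activity matrices, per behavior
naive_f1 <- function(a, b) {
  sapply(behavior_labels(), function(lb) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(a))) {
      if (a[i, lb] && b[i, lb]) tp <- tp + 1
      else if (!a[i, lb] && b[i, lb]) fp <- fp + 1
      else if (a[i, lb] && !b[i, lb]) fn <- fn + 1
    }
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  })
}

# a tiny complete keypoint track with all required bodyparts
make_track <- function(n = 50, fps = 20, px_per_mm = 20, drift = NULL) {
  parts <- feature_bodyparts()
  xy <- array(0, c(n, length(parts), 2),
              dimnames = list(NULL, parts, c("x", "y")))
  base <- seq(10, 10 + 5 * (length(parts) - 1), by = 5)
  for (i in seq_along(parts)) {
    xy[, i, 1] <- base[i]
    xy[, i, 2] <- i
  }
  if (!is.null(drift)) {
    xy[, , 1] <- xy[, , 1] + drift
    xy[, , 2] <- xy[, , 2] + drift
  }
  conf <- matrix(1, n, length(parts), dimnames = list(NULL, parts))
  keypoint_track(xy, conf, fps = fps, px_per_mm = px_per_mm)
}
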