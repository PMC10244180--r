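with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Embed a feature matrix into two dimensions
#'
#' Z-scores the feature columns (constant columns are dropped to zero),
#' trains a Barnes-Hut t-SNE on a random subsample of frames, and places
#' every remaining frame at the embedding coordinate of its nearest
#' training neighbor in feature space. Deterministic given `seed`.
#'
#' @param fm Numeric frames x features matrix (e.g. from
#'   [build_feature_matrix()]).
#' @param subsample Training subsample size (default 30000); when the input
#'   has fewer frames, all are used.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 30; reduced automatically
#'   for tiny inputs).
#' @param theta Barnes-Hut accuracy trade-off (default 0.5).
#' @return An `embedding_map`: list with `points` (frames x 2),
#'   `training_subsample` (frame indices), `seed`, `method_params`.
#' @export
embed_features <- function(fm, subsample = 30000, seed = 1,
                           perplexity = 30, theta = 0.5) {
  X <- apply(fm, 2, zscore)
  n <- nrow(X)
  with_seed(seed, {
    train <- if (n <= subsample) seq_len(n) else sort(sample.int(n, subsample))
    perp <- min(perplexity, floor((length(train) - 1) / 3))
    if (perp < 1) stop("too few frames to embed")
    ts <- Rtsne::Rtsne(X[train, , drop = FALSE], dims = 2,
                       perplexity = perp, theta = theta,
                       check_duplicates = FALSE, pca = TRUE,
                       verbose = FALSE, num_threads = 1)
    nn <- FNN::get.knnx(X[train, , drop = FALSE], X, k = 1)$nn.index[, 1]
    structure(list(points = ts$Y[nn, , drop = FALSE],
                   training_subsample = train, seed = seed,
                   method_params = list(perplexity = perp, theta = theta)),
              class = "embedding_map")
  })
}

#' Watershed segmentation of embedding density
#'
#' Estimates a Gaussian kernel density of the embedded points on a regular
#' grid, runs a watershed transform on the density surface (basins around
#' density modes), and assigns each frame to the basin containing its grid
#' cell. Basins holding fewer than `min_occupancy` of the frames are merged
#' into the nearest retained basin (by density-weighted centroid).
#'
#' @param em An `embedding_map`.
#' @param bandwidth KDE bandwidth in embedding units (scalar or length-2);
#'   default is a normal-reference (Scott-style) rule per axis.
#' @param grid Grid resolution per axis (default 512).
#' @param min_occupancy Minimum basin occupancy as a fraction of frames
#'   (default 0.005).
#' @param tolerance Watershed merge tolerance on the max-normalized density
#'   (default 0.05); shallower maxima (sampling ripple on a smooth mode)
#'   are absorbed.
#' @return A `cluster_map`: `labels` (integer per frame, 0 = unassigned),
#'   `density` (grid matrix), `grid_x`, `grid_y`, `n_clusters`.
#' @export
segment_density <- function(em, bandwidth = NULL, grid = 512,
                            min_occupancy = 0.005, tolerance = 0.05) {
  pts <- em$points
  if (nrow(unique(pts)) < 2L) stop("degenerate (all-identical) embedding")
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(pts[, 1]),
                   MASS::bandwidth.nrd(pts[, 2]))
    bandwidth[bandwidth <= 0] <- max(bandwidth, 1e-3)
  }
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, 2L)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  pad <- 2 * bandwidth
  lims <- c(range(pts[, 1]) + c(-1, 1) * pad[1],
            range(pts[, 2]) + c(-1, 1) * pad[2])
  kd <- MASS::kde2d(pts[, 1], pts[, 2], h = bandwidth, n = grid, lims = lims)
  dens <- kd$z / max(kd$z)
  dens[dens < 1e-4] <- 0
  ws <- EBImage::watershed(dens, tolerance = tolerance, ext = 1)
  ws <- matrix(as.integer(ws), nrow(dens), ncol(dens))
  ix <- findInterval(pts[, 1], kd$x, all.inside = TRUE)
  iy <- findInterval(pts[, 2], kd$y, all.inside = TRUE)
  # snap to the nearer grid node
  ix <- ix + (abs(kd$x[pmin(ix + 1L, grid)] - pts[, 1]) <
              abs(pts[, 1] - kd$x[ix]))
  iy <- iy + (abs(kd$y[pmin(iy + 1L, grid)] - pts[, 2]) <
              abs(pts[, 2] - kd$y[iy]))
  labels <- ws[cbind(ix, iy)]
  # merge under-occupied basins into the nearest retained basin
  occ <- table(factor(labels[labels > 0]))
  keep <- as.integer(names(occ))[occ / length(labels) >= min_occupancy]
  if (!length(keep))
    keep <- as.integer(names(occ))[which.max(occ)]
  cent <- t(vapply(keep, function(k)
    colMeans(pts[labels == k, , drop = FALSE]), numeric(2)))
  relab <- labels
  for (k in setdiff(unique(labels[labels > 0]), keep)) {
    sel <- labels == k
    ck <- colMeans(pts[sel, , drop = FALSE])
    tgt <- keep[which.min(colSums((t(cent) - ck)^2))]
    relab[sel] <- tgt
  }
  # compact ids to 1..K ordered by occupancy
  occ2 <- sort(table(factor(relab[relab > 0])), decreasing = TRUE)
  map <- stats::setNames(seq_along(occ2), names(occ2))
  out <- ifelse(relab > 0, map[as.character(relab)], 0L)
  structure(list(labels = as.integer(out), density = kd$z,
                 grid_x = kd$x, grid_y = kd$y,
                 n_clusters = length(occ2)),
            class = "cluster_map")
}

concat_frames <- function(ethograms) {
  lens <- vapply(ethograms, function(e) nrow(e$activity), integer(1))
  list(lens = lens, offsets = cumsum(c(0L, lens[-length(lens)])))
}

#' Egg-out-aligned cluster occupancy and significance
#'
#' For each cluster, computes the fraction of events in which the cluster
#' is expressed at each time point relative to completed egg expulsion,
#' over a full window of `window_full_s`. Significance uses a circular-
#' shift null: within each event the cluster label sequence is circularly
#' time-shifted by an independent uniform offset (preserving the labels'
#' autocorrelation), and the one-sided p-value is the add-one fraction of
#' null peak occupancies at least as large as the observed peak. A cluster
#' is called significant when p < `alpha` and its occupancy peaks within
#' `window_s` of egg out.
#'
#' @param cm A `cluster_map` whose `labels` cover the concatenated frames
#'   of `ethograms` (in order).
#' @param ethograms List of `ethogram` objects with `egg_out_frame`.
#' @param window_s Peak-timing window (default 20 s).
#' @param window_full_s Full occupancy window (default 60 s).
#' @param n_shift Number of circular shifts (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param smooth_s Moving-average smoothing of the occupancy time course
#'   before peak extraction, in seconds (default 0.5); applied to the
#'   observed and every null time course alike, it renders the peak
#'   statistic effectively continuous (avoiding the conservativeness of
#'   heavily tied discrete peaks).
#' @param seed Optional integer seed.
#' @return List with `stats` (data frame `cluster`, `occupancy`,
#'   `peak_occupancy`, `peak_time_s`, `p`, `significant`, ordered by peak
#'   time), `time_s` and `occupancy` (cluster x time matrix).
#' @export
cluster_significance <- function(cm, ethograms, window_s = 20,
                                 window_full_s = 60, n_shift = 1000,
                                 alpha = 0.05, smooth_s = 0.5,
                                 seed = NULL) {
  info <- concat_frames(ethograms)
  if (sum(info$lens) != length(cm$labels))
    stop("cluster labels do not cover the ethogram frames")
  anch <- vapply(ethograms, function(e)
    if (is.null(e$egg_out_frame)) NA_integer_ else e$egg_out_frame,
    integer(1))
  use <- which(!is.na(anch))
  if (!length(use)) stop("no egg_out anchors")
  fps <- ethograms[[use[1]]]$fps
  Wf <- round(window_full_s * fps)
  rel <- seq.int(-Wf, Wf)
  K <- cm$n_clusters
  ev_labs <- lapply(use, function(i)
    cm$labels[info$offsets[i] + seq_len(info$lens[i])])
  ev_anch <- anch[use]
  window_labels <- function(shifts) {
    t(vapply(seq_along(ev_labs), function(j) {
      lab <- ev_labs[[j]]
      ne <- length(lab)
      idx <- (ev_anch[j] + rel - shifts[j]) %% ne
      lab[idx + 1L]
    }, integer(length(rel))))
  }
  wsm <- max(1L, round(smooth_s * fps))
  if (wsm %% 2L == 0L) wsm <- wsm + 1L
  obs_mat <- window_labels(rep(0L, length(ev_labs)))
  occ <- t(vapply(seq_len(K), function(k)
    moving_average(colMeans(obs_mat == k), wsm), numeric(length(rel))))
  obs_peak <- apply(occ, 1, max)
  peak_t <- rel[apply(occ, 1, which.max)] / fps
  ge <- numeric(K)
  with_seed(seed, {
    for (b in seq_len(n_shift)) {
      sh <- vapply(ev_labs, function(l) sample.int(length(l), 1L), integer(1))
      m <- window_labels(sh)
      for (k in seq_len(K))
        ge[k] <- ge[k] +
          (max(moving_average(colMeans(m == k), wsm)) >= obs_peak[k] - 1e-12)
    }
  })
  p <- (1 + ge) / (1 + n_shift)
  st <- data.frame(cluster = seq_len(K),
                   occupancy = vapply(seq_len(K), function(k)
                     mean(cm$labels == k), numeric(1)),
                   peak_occupancy = obs_peak, peak_time_s = peak_t,
                   p = p,
                   significant = p < alpha & abs(peak_t) <= window_s)
  st <- st[order(st$peak_time_s), ]
  rownames(st) <- NULL
  list(stats = st, time_s = rel / fps, occupancy = occ)
}

#' Correspondence between clusters and manual behavior labels
#'
#' Frame-wise F1 between each cluster (as predictor) and each annotated
#' behavior (as reference), with each cluster assigned its best-matching
#' behavior by argmax F1; ties are broken toward the rarer behavior.
#'
#' @param cm A `cluster_map`.
#' @param ethograms List of `ethogram` objects whose concatenated frames
#'   match `cm$labels`.
#' @return List with `f1` (cluster x behavior matrix) and `assignment`
#'   (character vector, best behavior per cluster).
#' @export
cluster_correspondence <- function(cm, ethograms) {
  act <- do.call(rbind, lapply(ethograms, function(e) e$activity))
  if (nrow(act) != length(cm$labels))
    stop("frame counts do not match")
  K <- cm$n_clusters
  labs <- behavior_labels()
  f1 <- matrix(0, K, 7L, dimnames = list(paste0("cluster", seq_len(K)), labs))
  for (k in seq_len(K)) {
    pred <- cm$labels == k
    for (b in labs) {
      truth <- act[, b]
      tp <- sum(pred & truth); fp <- sum(pred & !truth)
      fn <- sum(!pred & truth)
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1[k, b] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    }
  }
  rarity <- colSums(act)
  assignment <- apply(f1, 1, function(row) {
    best <- which(row == max(row))
    labs[best[which.min(rarity[best])]]
  })
  list(f1 = f1, assignment = assignment)
}
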