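#' Extract the ordered start-event sequence from an ethogram
#'
#' Converts the bout view of an ethogram into the ordered list of behavior
#' onsets ("start events") used by the start-to-start transition analysis.
#' Three filters are applied: (i) proboscis-extension (pe) onsets closer
#' than `min_pe_spacing` (mm) to the previously counted pe location are
#' dropped (pe is only counted at distinct locations); (ii) pe onsets on
#' frames where any other behavior is active are dropped; (iii) bend onset
#' is counted once per sustained bend even when burrowing aborts and
#' restarts within it — this follows from the run-length bout encoding,
#' where a maintained bend is a single bout.
#'
#' Simultaneous onsets on one frame are ordered by a fixed priority
#' (egg_out > burrow > bend > detach > groom > pe > walk).
#'
#' @param e An `ethogram`.
#' @param min_pe_spacing Minimum spacing between counted pe onsets in mm
#'   (default 0.5). When positive but the ethogram carries no location
#'   track, the filter is skipped with a warning and this is recorded in
#'   the returned object's `provenance`.
#' @return A `start_sequence`: list with `event_id`, `fly_id`, `fps`,
#'   `items` (data frame `label`, `frame`) and `phase_split` (index of the
#'   egg_out item, or `NA` if none).
#' @export
extract_start_sequence <- function(e, min_pe_spacing = 0.5) {
  validate_ethogram(e)
  bouts <- to_bouts(e)
  prov <- character(0)
  items <- bouts[, c("label", "start")]
  names(items) <- c("label", "frame")
  pr <- match(items$label, onset_priority())
  items <- items[order(items$frame, pr), , drop = FALSE]
  # (ii) pe during any other active behavior
  if (nrow(items)) {
    is_pe <- items$label == "pe"
    if (any(is_pe)) {
      other <- rowSums(e$activity[, setdiff(behavior_labels(), "pe"),
                                  drop = FALSE]) > 0
      drop <- is_pe & other[items$frame + 1L]
      items <- items[!drop, , drop = FALSE]
    }
  }
  # (i) spatial spacing of pe onsets
  if (min_pe_spacing > 0 && any(items$label == "pe")) {
    if (is.null(e$location)) {
      warning("no location track: pe spacing filter skipped")
      prov <- c(prov, "pe_spacing_filter_skipped")
    } else {
      keep <- rep(TRUE, nrow(items))
      last_loc <- NULL
      for (i in seq_len(nrow(items))) {
        if (items$label[i] != "pe") next
        loc <- e$location[items$frame[i] + 1L, ]
        if (!is.null(last_loc) &&
            sqrt(sum((loc - last_loc)^2)) < min_pe_spacing) {
          keep[i] <- FALSE
        } else {
          last_loc <- loc
        }
      }
      items <- items[keep, , drop = FALSE]
    }
  }
  rownames(items) <- NULL
  n_egg <- sum(items$label == "egg_out")
  if (n_egg > 1L) stop("more than one egg_out onset in sequence")
  structure(list(event_id = e$event_id, fly_id = e$fly_id, fps = e$fps,
                 items = items,
                 phase_split = if (n_egg) which(items$label == "egg_out")
                               else NA_integer_,
                 provenance = prov),
            class = "start_sequence")
}

# Items of one phase of a sequence. The egg_out item is the boundary and is
# included in both phases, so the transition into egg_out is a pre-phase
# pair and the transition out of it a post-phase pair.
phase_items <- function(s, phase) {
  it <- s$items
  if (phase == "all" || is.na(s$phase_split)) {
    if (phase == "post" && is.na(s$phase_split)) return(it[0, , drop = FALSE])
    return(it)
  }
  k <- s$phase_split
  switch(phase,
         pre  = it[seq_len(k), , drop = FALSE],
         post = it[seq.int(k, nrow(it)), , drop = FALSE],
         stop("phase must be 'pre', 'post' or 'all'"))
}

#' Estimate the pooled start-to-start transition matrix
#'
#' Counts consecutive (label_i -> label_j) onset pairs pooled over
#' sequences, then row-normalizes. Self-transitions are counted: a behavior
#' that starts, stops and starts again without any intervening onset
#' contributes to the diagonal. Pre- and post-expulsion phases are tallied
#' separately when requested.
#'
#' @param seqs List of `start_sequence` objects.
#' @param phase `"all"`, `"pre"` (up to and including egg_out) or `"post"`
#'   (from egg_out onward).
#' @return A `transition_matrix`: list with 7x7 `counts`, row-stochastic
#'   `probs` (all-zero rows stay zero), `initial_distribution` (fraction of
#'   sequences starting with each label), `phase`, `n_sequences`; `pvals`,
#'   `significant` and `n_perm` are filled by [permutation_test()].
#' @export
estimate_transitions <- function(seqs, phase = c("all", "pre", "post")) {
  phase <- match.arg(phase)
  if (!length(seqs)) stop("need at least one sequence")
  labs <- behavior_labels()
  counts <- matrix(0L, 7L, 7L, dimnames = list(labs, labs))
  init <- stats::setNames(numeric(7), labs)
  n_used <- 0L
  for (s in seqs) {
    it <- phase_items(s, phase)
    if (!nrow(it)) next
    n_used <- n_used + 1L
    init[it$label[1]] <- init[it$label[1]] + 1
    if (nrow(it) > 1L) {
      fr <- match(it$label[-nrow(it)], labs)
      to <- match(it$label[-1], labs)
      tab <- tabulate((fr - 1L) * 7L + to, nbins = 49L)
      counts <- counts + matrix(tab, 7L, 7L, byrow = TRUE)
    }
  }
  if (sum(counts) == 0L) stop("no transitions in pooled ", phase, " phase")
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  structure(list(labels = labs, counts = counts, probs = probs,
                 pvals = NULL, significant = NULL, phase = phase,
                 n_perm = 0L, alpha = NA_real_, prob_floor = NA_real_,
                 initial_distribution = init / max(n_used, 1L),
                 n_sequences = n_used),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> phase=%s, %d sequences, %d transitions\n",
              x$phase, x$n_sequences, sum(x$counts)))
  print(round(x$probs, 3))
  if (!is.null(x$pvals))
    cat(sprintf("permutation test: n_perm=%d, alpha=%g, prob_floor=%g; %d significant cells\n",
                x$n_perm, x$alpha, x$prob_floor, sum(x$significant)))
  invisible(x)
}

#' One-sided permutation test for transition probabilities
#'
#' Tests each cell of an observed start-to-start transition matrix against a
#' null in which the label order is independently and uniformly shuffled
#' within each sequence (phase-respecting), preserving every sequence's
#' label multiset and length. The one-sided p-value for a cell uses the
#' add-one estimator p = (1 + #\{permuted prob >= observed prob\}) /
#' (1 + n_perm). A cell is flagged significant when p < `alpha` AND its
#' observed probability is at least `prob_floor` (low-probability
#' transitions are never flagged).
#'
#' @param observed A `transition_matrix` from [estimate_transitions()].
#' @param seqs The same list of `start_sequence` objects.
#' @param n_perm Number of shuffles (default 10000).
#' @param alpha Significance level (default 0.001).
#' @param prob_floor Minimum observed probability for significance
#'   (default 0.04).
#' @param seed Optional integer seed; results are deterministic given it.
#' @return The `transition_matrix` with `pvals` and `significant` filled.
#' @export
permutation_test <- function(observed, seqs, n_perm = 10000, alpha = 0.001,
                             prob_floor = 0.04, seed = NULL) {
  stopifnot(inherits(observed, "transition_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  labs <- behavior_labels()
  phase <- observed$phase
  lab_int <- integer(0); sid <- integer(0)
  for (i in seq_along(seqs)) {
    it <- phase_items(seqs[[i]], phase)
    if (nrow(it) < 2L) next
    lab_int <- c(lab_int, match(it$label, labs))
    sid <- c(sid, rep.int(i, nrow(it)))
  }
  n <- length(lab_int)
  if (n < 2L) stop("not enough pooled items for permutation")
  keep <- sid[-n] == sid[-1]
  obs <- observed$probs
  ge <- matrix(0L, 7L, 7L)
  for (b in seq_len(n_perm)) {
    per <- lab_int[order(sid, stats::runif(n))]
    fr <- per[-n][keep]; to <- per[-1][keep]
    cnt <- matrix(tabulate((fr - 1L) * 7L + to, 49L), 7L, 7L, byrow = TRUE)
    rs <- rowSums(cnt)
    pp <- cnt / ifelse(rs > 0, rs, 1)
    ge <- ge + (pp >= obs - 1e-12)
  }
  pv <- (1 + ge) / (1 + n_perm)
  dimnames(pv) <- dimnames(obs)
  observed$pvals <- pv
  observed$significant <- (pv < alpha) & (obs >= prob_floor)
  observed$n_perm <- as.integer(n_perm)
  observed$alpha <- alpha
  observed$prob_floor <- prob_floor
  observed
}

#' First-occurrence ordering of the seven behaviors
#'
#' For sequences containing all seven behaviors, ranks each behavior's first
#' onset and tabulates, per behavior, the fraction of events in which it was
#' the k-th component to appear. Sequences missing any component are
#' excluded from the denominator.
#'
#' @param seqs List of `start_sequence` objects.
#' @return List with `fractions` (7 labels x 7 ordinal positions, each row
#'   summing to 1) and `n_events` (number of retained sequences).
#' @export
first_occurrence_order <- function(seqs) {
  labs <- behavior_labels()
  tab <- matrix(0, 7L, 7L, dimnames = list(labs, paste0("pos", 1:7)))
  n_used <- 0L
  for (s in seqs) {
    it <- s$items
    first <- vapply(labs, function(lb) {
      i <- which(it$label == lb)[1]
      if (is.na(i)) NA_real_ else i
    }, numeric(1))
    if (anyNA(first)) next
    n_used <- n_used + 1L
    pos <- rank(first, ties.method = "first")
    tab[cbind(seq_len(7L), pos)] <- tab[cbind(seq_len(7L), pos)] + 1
  }
  if (n_used == 0L) stop("no sequence contains all seven behaviors")
  list(fractions = tab / n_used, n_events = n_used)
}

#' Egg-out-aligned behavior time course
#'
#' Average time course of the seven behaviors as the instantaneous fraction
#' of events in which each behavior is active, aligned so that t = 0 marks
#' completed egg expulsion. The denominator at each relative time point is
#' the number of events whose recording covers that point.
#'
#' @param ethograms List of `ethogram` objects, each with `egg_out_frame`.
#' @param window_s Half-window in seconds (default 60; time axis spans
#'   -window_s .. +window_s).
#' @return List with `time_s`, `fraction` (7 labels x time matrix in
#'   \[0,1\]) and `n_events`.
#' @export
behavior_time_course <- function(ethograms, window_s = 60) {
  use <- Filter(function(e) !is.null(e$egg_out_frame), ethograms)
  if (!length(use)) stop("no ethogram has an egg_out_frame")
  fps <- use[[1]]$fps
  if (!all(vapply(use, function(e) e$fps, numeric(1)) == fps))
    stop("all ethograms must share one frame rate")
  W <- round(window_s * fps)
  rel <- seq.int(-W, W)
  num <- matrix(0, 7L, length(rel), dimnames = list(behavior_labels(), NULL))
  den <- numeric(length(rel))
  for (e in use) {
    fr <- e$egg_out_frame + rel
    ok <- fr >= 0L & fr < nrow(e$activity)
    den[ok] <- den[ok] + 1
    num[, ok] <- num[, ok] + t(e$activity[fr[ok] + 1L, , drop = FALSE])
  }
  list(time_s = rel / fps,
       fraction = num / rep(pmax(den, 1), each = 7L),
       n_events = length(use))
}

#' Per-fly probability of progression between sequence components
#'
#' Two progression statistics are supported: bend -> burrow (fraction of
#' bend bouts during which at least one burrow onset occurs) and
#' burrow -> egg_out (fraction of burrow bouts containing completed egg
#' expulsion). Bouts are pooled across a fly's events; flies with fewer
#' than `min_bouts` source bouts are excluded.
#'
#' @param ethograms List of `ethogram` objects.
#' @param from,to Behavior pair: `("bend","burrow")` or
#'   `("burrow","egg_out")`.
#' @param min_bouts Minimum number of `from` bouts per fly (default 3).
#' @return Data frame `fly_id`, `n_bouts`, `n_progressed`, `probability`.
#' @export
progression_probability <- function(ethograms, from, to, min_bouts = 3) {
  pair <- paste(from, to, sep = "->")
  if (!pair %in% c("bend->burrow", "burrow->egg_out"))
    stop("unsupported pair: ", pair)
  per_bout <- lapply(ethograms, function(e) {
    b <- to_bouts(e)
    src <- b[b$label == from, , drop = FALSE]
    if (!nrow(src)) return(NULL)
    hit <- if (pair == "bend->burrow") {
      starts <- b$start[b$label == "burrow"]
      vapply(seq_len(nrow(src)), function(i)
        any(starts >= src$start[i] & starts < src$end[i]), logical(1))
    } else {
      f <- e$egg_out_frame
      if (is.null(f)) rep(FALSE, nrow(src))
      else f >= src$start & f <= src$end
    }
    data.frame(fly_id = e$fly_id, hit = hit)
  })
  per_bout <- do.call(rbind, per_bout)
  if (is.null(per_bout)) stop("no '", from, "' bouts in input")
  agg <- stats::aggregate(hit ~ fly_id, per_bout,
                          function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(fly_id = agg$fly_id,
                    n_bouts = agg$hit[, "n"], n_progressed = agg$hit[, "k"])
  out <- out[out$n_bouts >= min_bouts, , drop = FALSE]
  out$probability <- out$n_progressed / out$n_bouts
  rownames(out) <- NULL
  out
}
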