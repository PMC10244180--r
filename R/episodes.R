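#' Segment burrowing episodes and attach cycles
#'
#' One episode per maximal burrow bout. Annotated cycle frames are
#' partitioned into their containing episode; a cycle frame outside every
#' burrow bout is a validation error. An episode's outcome is `expel` when
#' completed egg expulsion falls within its frame range (inclusive at both
#' ends), otherwise `abort`.
#'
#' @param e An `ethogram`.
#' @return Data frame with `fly_id`, `event_id`, `start`, `end` (0-based,
#'   half-open), `duration_s`, `n_cycles`, `outcome`.
#' @export
segment_burrow_episodes <- function(e) {
  validate_ethogram(e)
  b <- to_bouts(e)
  b <- b[b$label == "burrow", , drop = FALSE]
  if (!nrow(b))
    return(data.frame(fly_id = character(0), event_id = character(0),
                      start = integer(0), end = integer(0),
                      duration_s = numeric(0), n_cycles = integer(0),
                      outcome = character(0)))
  n_cyc <- integer(nrow(b))
  if (length(e$cycle_frames)) {
    idx <- findInterval(e$cycle_frames, b$start)
    inside <- idx >= 1 & e$cycle_frames < b$end[pmax(idx, 1L)]
    if (!all(inside)) stop("cycle frame outside any burrow bout")
    n_cyc <- tabulate(idx, nbins = nrow(b))
  }
  f <- e$egg_out_frame
  expel <- if (is.null(f)) rep(FALSE, nrow(b)) else f >= b$start & f <= b$end
  data.frame(fly_id = e$fly_id, event_id = e$event_id,
             start = b$start, end = b$end, duration_s = b$duration_s,
             n_cycles = n_cyc,
             outcome = ifelse(expel, "expel", "abort"))
}

#' Cycle statistics of burrowing episodes
#'
#' Pooled cycle-count distributions and per-fly mean cycle counts, computed
#' separately for aborted and egg-expulsion episodes, plus the Pearson
#' correlation between an episode's cycle count and its duration over all
#' episodes. For the per-fly means, only flies with at least `min_episodes`
#' episodes of the given outcome are retained.
#'
#' @param episodes Data frame as returned by [segment_burrow_episodes()]
#'   (rows may be pooled over flies/events).
#' @param min_episodes Minimum episodes per fly and outcome (default 2).
#' @return List with `per_fly` (data frame `fly_id`, `outcome`,
#'   `n_episodes`, `mean_cycles`), `pooled` (cycle-count tables by outcome),
#'   and `r_cycles_duration` (Pearson r; `NA` with fewer than 2 episodes).
#' @export
burrow_cycle_stats <- function(episodes, min_episodes = 2) {
  if (!nrow(episodes)) stop("empty episode table")
  agg <- stats::aggregate(n_cycles ~ fly_id + outcome, episodes,
                          function(x) c(n = length(x), m = mean(x)))
  per_fly <- data.frame(fly_id = agg$fly_id, outcome = agg$outcome,
                        n_episodes = agg$n_cycles[, "n"],
                        mean_cycles = agg$n_cycles[, "m"])
  per_fly <- per_fly[per_fly$n_episodes >= min_episodes, , drop = FALSE]
  rownames(per_fly) <- NULL
  pooled <- lapply(split(episodes$n_cycles, episodes$outcome), table)
  r <- if (nrow(episodes) >= 2 && stats::sd(episodes$n_cycles) > 0 &&
           stats::sd(episodes$duration_s) > 0)
    stats::cor(episodes$n_cycles, episodes$duration_s) else NA_real_
  list(per_fly = per_fly, pooled = pooled, r_cycles_duration = r)
}

#' Per-fly egg output, depth, wall and drop summaries
#'
#' Normalized egg depth scores eggs as 1 (fully subterraneous), 0.5
#' (partially subterraneous) or 0 (resting on the surface); the mean is
#' taken per fly. Wall fraction is the fraction of a fly's eggs deposited
#' on chamber walls; dropped fraction is the fraction expelled without
#' burrowing. Each metric has its own minimum egg count; flies under it
#' get `NA` for that metric.
#'
#' @param records Data frame with columns `fly_id`, `depth` (0, 0.5 or 1),
#'   `location` (`"substrate"` or `"wall"`), `mode` (`"burrowed"` or
#'   `"dropped"`), and optionally `substrate_pct`.
#' @param min_eggs Named list of per-metric minima; defaults
#'   `list(depth = 1, wall = 3, dropped = 4)`.
#' @return Data frame `fly_id`, `n_eggs`, `mean_depth`, `wall_fraction`,
#'   `dropped_fraction` (and `substrate_pct` when present in the input).
#' @export
egg_output_summary <- function(records,
                               min_eggs = list(depth = 1, wall = 3,
                                               dropped = 4)) {
  if (!nrow(records)) stop("empty egg record set")
  if (!all(records$depth %in% c(0, 0.5, 1)))
    stop("depth scores must be 0, 0.5 or 1")
  sp <- split(records, records$fly_id)
  out <- do.call(rbind, lapply(sp, function(r) {
    n <- nrow(r)
    data.frame(
      fly_id = r$fly_id[1], n_eggs = n,
      mean_depth = if (n >= min_eggs$depth) mean(r$depth) else NA_real_,
      wall_fraction = if (n >= min_eggs$wall)
        mean(r$location == "wall") else NA_real_,
      dropped_fraction = if (n >= min_eggs$dropped)
        mean(r$mode == "dropped") else NA_real_,
      substrate_pct = if ("substrate_pct" %in% names(r))
        r$substrate_pct[1] else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Construct a photostimulation trial record
#'
#' @param light_on,light_off Stimulus onset/offset in seconds
#'   (`light_on < light_off`).
#' @param pulse_offsets Offsets (s) of individual light pulses; defaults to
#'   `light_off` (single continuous pulse).
#' @param egg_out_time Optional completed-expulsion time (s).
#' @return A `stim_trial` list.
#' @export
stim_trial <- function(light_on, light_off, pulse_offsets = light_off,
                       egg_out_time = NULL) {
  if (light_on >= light_off) stop("light_on must precede light_off")
  structure(list(light_on = light_on, light_off = light_off,
                 pulse_offsets = sort(pulse_offsets),
                 egg_out_time = egg_out_time),
            class = "stim_trial")
}

#' Classify the post-expulsion outcome of a photostimulation trial
#'
#' After completed egg expulsion, a fly either advances to the reset phase
#' or reverts to earlier components of the sequence. The rule: the
#' expelling burrow episode is the one containing egg_out; the fly
#' `advance`s if no further burrow onset occurs within `reset_gap_s`
#' seconds of that episode's end (the reset window opens there); otherwise
#' it `revert`s, and the reset is anchored at the onset of the last burrow
#' episode that precedes a `reset_gap_s`-long burrow-free window. Burrow
#' stop time is reported relative to egg expulsion, using the expelling
#' episode's end as a proxy for ovipositor detachment onset.
#'
#' Independently, the expelled-after-stimulation flag is true when the trial
#' records egg expulsion no later than `expel_window_s` seconds after the
#' last pulse offset.
#'
#' @param e An `ethogram` with `egg_out_frame` (may be `NULL` for flag-only
#'   scoring when `trial$egg_out_time` is set).
#' @param trial A `stim_trial`, or `NULL` when only the advance/revert
#'   classification is wanted.
#' @param reset_gap_s Burrow-free window defining reset (default 65 s).
#' @param expel_window_s Window after the last pulse offset within which an
#'   expulsion counts as stimulus-evoked (default 4 s).
#' @return List with `category` (`"advance"`/`"revert"`, or `NA` without
#'   egg_out), `stop_after_egg_out_s`, `reset_time` (s; for `advance` the
#'   expelling episode's end, for `revert` the onset of the anchoring
#'   episode; `NA` if the recording ends before a full gap is observed),
#'   and `expelled_after_stim` (logical or `NA` without a trial).
#' @export
classify_post_expulsion <- function(e, trial = NULL, reset_gap_s = 65,
                                    expel_window_s = 4) {
  flag <- NA
  if (!is.null(trial)) {
    stopifnot(inherits(trial, "stim_trial"))
    if (!is.null(trial$egg_out_time))
      flag <- trial$egg_out_time <=
        max(trial$pulse_offsets) + expel_window_s
  }
  if (is.null(e$egg_out_frame)) {
    if (is.na(flag)) stop("no egg_out available for outcome classification")
    return(list(category = NA_character_, stop_after_egg_out_s = NA_real_,
                reset_time = NA_real_, expelled_after_stim = flag))
  }
  ep <- segment_burrow_episodes(e)
  i_expel <- which(ep$outcome == "expel")
  if (!length(i_expel)) stop("egg_out falls outside every burrow episode")
  i_expel <- i_expel[1]
  fps <- e$fps
  t_egg <- e$egg_out_frame / fps
  expel_end <- ep$end[i_expel] / fps
  later <- ep[ep$start / fps > expel_end, , drop = FALSE]
  gap_frames <- reset_gap_s * fps
  t_end <- nrow(e$activity) / fps
  if (!nrow(later) || later$start[1] / fps - expel_end >= reset_gap_s) {
    # reset window opens at the expelling episode's end
    category <- "advance"
    reset_time <- if (t_end - expel_end >= reset_gap_s ||
                      !nrow(later)) expel_end else NA_real_
  } else {
    category <- "revert"
    gaps_to <- c(later$start[-1] / fps, t_end)
    free <- gaps_to - later$end / fps
    ok <- which(free >= reset_gap_s)
    reset_time <- if (length(ok))
      later$start[ok[length(ok)]] / fps else NA_real_
  }
  list(category = category,
       stop_after_egg_out_s = expel_end - t_egg,
       reset_time = reset_time,
       expelled_after_stim = flag)
}
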