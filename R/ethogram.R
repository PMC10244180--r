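#' The seven annotated behaviors of the egg-laying sequence
#'
#' Canonical label set, in fixed order: proboscis extension (`pe`), `walk`,
#' abdominal `bend`, ovipositor `burrow`, completed egg expulsion (`egg_out`,
#' a point-like one-frame event), `detach` and `groom`.
#'
#' @return Character vector of length 7.
#' @export
behavior_labels <- function() {
  c("pe", "walk", "bend", "burrow", "egg_out", "detach", "groom")
}

# priority used to order simultaneous same-frame onsets (highest first)
onset_priority <- function() {
  c("egg_out", "burrow", "bend", "detach", "groom", "pe", "walk")
}

#' Construct a frame-wise multi-label ethogram
#'
#' An ethogram is a frame x behavior boolean activity matrix over the seven
#' annotated behaviors, at a fixed frame rate. The representation is
#' multi-label: `bend` may be active simultaneously with `burrow`, `egg_out`
#' and `detach` (abdominal bending is maintained throughout those actions),
#' whereas `walk` may never be co-active with `burrow`. Frames are 0-based
#' throughout the package; row `i` of `activity` is frame `i - 1`.
#'
#' @param activity Logical matrix (frames x 7) with column names
#'   `behavior_labels()`, or a matrix coercible to logical.
#' @param fps Frame rate in frames/second (> 0, default 20).
#' @param fly_id,event_id Identifier strings.
#' @param egg_out_frame Optional 0-based frame index of completed egg
#'   expulsion; must carry an active `egg_out` bit.
#' @param cycle_frames Optional ordered 0-based frame indices of annotated
#'   burrow cycles; each must fall on a burrow-active frame.
#' @param location Optional frames x 2 numeric matrix of (x, y) positions in
#'   mm, used by spacing-dependent filters; filters degrade gracefully (with
#'   a warning) when absent.
#' @return An object of class `ethogram`.
#' @export
ethogram <- function(activity, fps = 20, fly_id = "fly", event_id = "event",
                     egg_out_frame = NULL, cycle_frames = integer(0),
                     location = NULL) {
  if (is.null(dim(activity)) || ncol(activity) != 7L)
    stop("`activity` must be a frames x 7 matrix")
  if (is.null(colnames(activity))) colnames(activity) <- behavior_labels()
  if (!identical(colnames(activity), behavior_labels()))
    activity <- activity[, behavior_labels(), drop = FALSE]
  mode(activity) <- "logical"
  if (anyNA(activity)) stop("`activity` contains NA")
  e <- structure(list(
    fly_id = as.character(fly_id), event_id = as.character(event_id),
    fps = as.numeric(fps), activity = activity,
    egg_out_frame = if (is.null(egg_out_frame)) NULL else as.integer(egg_out_frame),
    cycle_frames = as.integer(cycle_frames),
    location = location
  ), class = "ethogram")
  validate_ethogram(e)
  e
}

#' Validate an ethogram
#'
#' Checks the structural invariants: positive frame rate, no walk/burrow
#' co-activity, egg_out active at `egg_out_frame`, and every annotated cycle
#' frame inside a burrow-active frame.
#'
#' @param e An `ethogram`.
#' @return `e`, invisibly; errors on violation.
#' @export
validate_ethogram <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  if (!is.numeric(e$fps) || length(e$fps) != 1L || e$fps <= 0)
    stop("fps must be a single positive number")
  a <- e$activity
  n <- nrow(a)
  if (any(a[, "walk"] & a[, "burrow"]))
    stop("walk and burrow may not be simultaneously active")
  if (!is.null(e$egg_out_frame)) {
    f <- e$egg_out_frame
    if (f < 0L || f >= n) stop("egg_out_frame outside recording")
    if (!a[f + 1L, "egg_out"]) stop("egg_out not active at egg_out_frame")
  }
  if (length(e$cycle_frames)) {
    if (is.unsorted(e$cycle_frames)) stop("cycle_frames must be ordered")
    if (any(e$cycle_frames < 0L | e$cycle_frames >= n))
      stop("cycle_frames outside recording")
    if (!all(a[e$cycle_frames + 1L, "burrow"]))
      stop("cycle frame outside any burrow bout")
  }
  if (!is.null(e$location)) {
    if (nrow(e$location) != n || ncol(e$location) != 2L)
      stop("location must be a frames x 2 matrix")
  }
  invisible(e)
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> fly %s / event %s: %d frames @ %g fps (%.1f s)\n",
              x$fly_id, x$event_id, nrow(x$activity), x$fps,
              nrow(x$activity) / x$fps))
  act <- colSums(x$activity)
  cat("  active frames:", paste(sprintf("%s=%d", names(act), act),
                                collapse = " "), "\n")
  if (!is.null(x$egg_out_frame))
    cat(sprintf("  egg_out at frame %d (%.2f s); %d burrow cycles annotated\n",
                x$egg_out_frame, x$egg_out_frame / x$fps,
                length(x$cycle_frames)))
  invisible(x)
}

#' Run-length (bout) view of an ethogram
#'
#' Encodes each behavior column as maximal half-open runs `[start, end)` of
#' activity, in 0-based frames. Concatenating the bout frame ranges per label
#' reproduces the activity matrix exactly.
#'
#' @param e An `ethogram`.
#' @return A data frame with columns `label`, `start`, `end` (0-based,
#'   half-open) and `duration_s`, sorted by label then start.
#' @export
to_bouts <- function(e) {
  validate_ethogram(e)
  out <- lapply(behavior_labels(), function(lb) {
    col <- e$activity[, lb]
    if (!any(col)) return(NULL)
    r <- rle(as.vector(col))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(label = lb, start = starts[keep], end = ends[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(label = character(0), start = integer(0),
                      end = integer(0), duration_s = numeric(0)))
  out$duration_s <- (out$end - out$start) / e$fps
  rownames(out) <- NULL
  out
}

#' Rebuild an activity matrix from bouts
#'
#' Inverse of [to_bouts()]: paints each bout's half-open frame range back
#' into a frames x 7 logical matrix.
#'
#' @param bouts Data frame with `label`, `start`, `end` (0-based half-open).
#' @param n_frames Number of frames of the output matrix.
#' @return Logical matrix (frames x 7).
#' @export
bouts_to_activity <- function(bouts, n_frames) {
  a <- matrix(FALSE, n_frames, 7L, dimnames = list(NULL, behavior_labels()))
  for (i in seq_len(nrow(bouts))) {
    rng <- seq.int(bouts$start[i] + 1L, bouts$end[i])
    a[rng, bouts$label[i]] <- TRUE
  }
  a
}

ethogram_sidecar_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".json", path)
  else paste0(path, ".json")
}

#' Read an ethogram from CSV
#'
#' The on-disk schema is one row per (frame, active behavior) with header
#' `frame,behavior`; multi-label frames appear as several rows sharing a
#' frame index. A sidecar JSON next to the CSV (same stem, `.json`), if
#' present, supplies `fly_id`, `event_id`, `fps`, `egg_out_frame`,
#' `cycle_frames` and `n_frames`; otherwise `fps` is taken from the argument
#' and the frame count from the maximal frame index.
#'
#' @param path CSV file path.
#' @param fps Frame rate used when no sidecar is present (default 20).
#' @return An `ethogram`.
#' @export
load_ethogram <- function(path, fps = 20) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("frame", "behavior")))
    stop("ethogram CSV must have header `frame,behavior`")
  bad <- !df$behavior %in% behavior_labels()
  if (any(bad))
    stop("unknown behavior name in row(s) ",
         paste(which(bad) + 1L, collapse = ", "), ": ",
         paste(unique(df$behavior[bad]), collapse = ", "))
  if (nrow(df) && (anyNA(df$frame) || any(df$frame < 0) ||
                   any(df$frame != floor(df$frame))))
    stop("frame indices must be non-negative integers")
  meta <- list()
  sc <- ethogram_sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  n <- if (!is.null(meta$n_frames)) as.integer(meta$n_frames)
       else if (nrow(df)) max(df$frame) + 1L else 0L
  a <- matrix(FALSE, n, 7L, dimnames = list(NULL, behavior_labels()))
  if (nrow(df)) a[cbind(df$frame + 1L, match(df$behavior, behavior_labels()))] <- TRUE
  ethogram(a,
           fps = if (!is.null(meta$fps)) meta$fps else fps,
           fly_id = if (!is.null(meta$fly_id)) meta$fly_id else "fly",
           event_id = if (!is.null(meta$event_id)) meta$event_id else "event",
           egg_out_frame = meta$egg_out_frame,
           cycle_frames = if (!is.null(meta$cycle_frames))
             unlist(meta$cycle_frames) else integer(0))
}

#' Write an ethogram to CSV (plus sidecar JSON)
#'
#' @param e An `ethogram`.
#' @param path Output CSV path; the sidecar JSON is written next to it.
#' @return `path`, invisibly.
#' @export
save_ethogram <- function(e, path) {
  validate_ethogram(e)
  idx <- which(e$activity, arr.ind = TRUE)
  df <- data.frame(frame = idx[, 1] - 1L,
                   behavior = behavior_labels()[idx[, 2]])
  df <- df[order(df$frame, match(df$behavior, behavior_labels())), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(fly_id = e$fly_id, event_id = e$event_id, fps = e$fps,
               n_frames = nrow(e$activity), cycle_frames = e$cycle_frames)
  if (!is.null(e$egg_out_frame)) meta$egg_out_frame <- e$egg_out_frame
  jsonlite::write_json(meta, ethogram_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
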