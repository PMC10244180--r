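#' Expand sparse point-event labels to a fixed width
#'
#' Point-like labels (natively one frame, e.g. proboscis extension and egg
#' out) are dilated symmetrically to `width` frames around each active
#' frame, clipped at the recording bounds. Used before computing
#' frame-wise agreement so that one-frame timing offsets are not scored as
#' disagreement.
#'
#' @param e An `ethogram`.
#' @param labels Labels to expand (default `c("pe", "egg_out")`).
#' @param width Odd target width in frames (default 3).
#' @return A new `ethogram` with the expanded activity.
#' @export
expand_sparse_labels <- function(e, labels = c("pe", "egg_out"), width = 3) {
  if (width %% 2 != 1) stop("width must be odd")
  validate_ethogram(e)
  if (width == 1) return(e)
  h <- (width - 1) / 2
  a <- e$activity
  n <- nrow(a)
  for (lb in labels) {
    act <- which(a[, lb])
    for (f in act) {
      rng <- max(1L, f - h):min(n, f + h)
      a[rng, lb] <- TRUE
    }
  }
  e$activity <- a
  e
}

#' Frame-wise confusion counts between two ethograms
#'
#' Per behavior, counts frames scored active in both (`tp`), only in the
#' comparison (`fp`), and only in the reference (`fn`), plus pooled totals
#' across behaviors.
#'
#' @param ref Reference `ethogram`.
#' @param cmp Comparison `ethogram` with equal frame count.
#' @return A `confusion_table`: data frame with one row per behavior and a
#'   `combined` attribute row of pooled counts.
#' @export
confusion_counts <- function(ref, cmp) {
  if (nrow(ref$activity) != nrow(cmp$activity))
    stop("frame counts differ")
  out <- do.call(rbind, lapply(behavior_labels(), function(lb) {
    a <- ref$activity[, lb]; b <- cmp$activity[, lb]
    data.frame(behavior = lb, tp = sum(a & b), fp = sum(!a & b),
               fn = sum(a & !b))
  }))
  attr(out, "combined") <- data.frame(behavior = "combined",
                                      tp = sum(out$tp), fp = sum(out$fp),
                                      fn = sum(out$fn))
  class(out) <- c("confusion_table", class(out))
  out
}

f1_from_counts <- function(tp, fp, fn) {
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, f1 = f1)
}

#' Precision, recall and F1 agreement from confusion counts
#'
#' F1 = 2 * precision * recall / (precision + recall), with the 0/0 case
#' scored 0 by convention. The combined score is micro-averaged (computed
#' from counts pooled across behaviors); a macro average (mean of
#' per-behavior F1) is also reported.
#'
#' @param ct A `confusion_table` from [confusion_counts()].
#' @return An `agreement_report`: list with `per_behavior` (data frame) and
#'   `combined` (micro-averaged precision/recall/F1 plus `macro_f1`).
#' @export
f1_agreement <- function(ct) {
  per <- cbind(ct[, "behavior", drop = FALSE],
               t(mapply(f1_from_counts, ct$tp, ct$fp, ct$fn)))
  cmb <- attr(ct, "combined")
  comb <- f1_from_counts(cmb$tp, cmb$fp, cmb$fn)
  structure(list(per_behavior = per,
                 combined = c(comb, macro_f1 = mean(per$f1))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  print(cbind(x$per_behavior[1],
              round(x$per_behavior[-1], 3)), row.names = FALSE)
  cat(sprintf("combined (micro): precision %.3f recall %.3f F1 %.3f; macro F1 %.3f\n",
              x$combined["precision"], x$combined["recall"],
              x$combined["f1"], x$combined["macro_f1"]))
  invisible(x)
}
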