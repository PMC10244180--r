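#' Bodyparts consumed by the feature extractor
#'
#' @return Character vector of the 13 tracked landmarks.
#' @export
feature_bodyparts <- function() {
  c("scutellum", "ocellus", "proboscis_tip", "stripe_A2", "stripe_A5",
    "stripe_A6", "leg_T1", "leg_T2", "leg_T3", "ovipositor", "T6_edge",
    "egg_tip", "analia_base")
}

#' Construct a keypoint track
#'
#' @param xy Numeric array frames x bodyparts x 2 (x, y in pixels), with
#'   bodypart dimnames.
#' @param confidence Frames x bodyparts matrix of tracker likelihoods in
#'   \[0, 1\].
#' @param fps Frame rate (frames/second).
#' @param px_per_mm Spatial calibration (pixels per mm).
#' @param interpolated Optional list (per bodypart) of interpolated frame
#'   spans, kept as provenance.
#' @return A `keypoint_track`.
#' @export
keypoint_track <- function(xy, confidence, fps, px_per_mm,
                           interpolated = list()) {
  stopifnot(length(dim(xy)) == 3L, dim(xy)[3] == 2L,
            nrow(confidence) == dim(xy)[1],
            ncol(confidence) == dim(xy)[2])
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]")
  structure(list(xy = xy, confidence = confidence, fps = fps,
                 px_per_mm = px_per_mm, interpolated = interpolated),
            class = "keypoint_track")
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("<keypoint_track> %d frames @ %g fps, %d bodyparts, %g px/mm\n",
              dim(x$xy)[1], x$fps, dim(x$xy)[2], x$px_per_mm))
  invisible(x)
}

#' Read a pose-estimation keypoint CSV
#'
#' Consumes the standard three-header-row keypoint CSV dialect (scorer row,
#' bodypart row, coordinate row; per bodypart an `x`, `y`, `likelihood`
#' column triplet; first column a frame index). Frames whose likelihood
#' falls below `min_confidence` have their coordinates linearly
#' interpolated from the neighboring confident frames; leading/trailing
#' gaps are held at the nearest valid value. Raw likelihoods are preserved
#' (the egg-emergence feature passes them through).
#'
#' @param path CSV path.
#' @param px_per_mm Pixels per mm.
#' @param fps Frame rate (default 20).
#' @param min_confidence Interpolation threshold in \[0, 1\] (default 0.9).
#' @return A `keypoint_track` whose `interpolated` field records the
#'   repaired spans per bodypart.
#' @export
read_keypoints <- function(path, px_per_mm, fps = 20, min_confidence = 0.9) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 3L) stop("malformed keypoint CSV: missing header rows")
  parts_row <- as.character(unlist(raw[2, -1]))
  coords_row <- as.character(unlist(raw[3, -1]))
  if (!all(coords_row %in% c("x", "y", "likelihood")))
    stop("malformed keypoint CSV: third header row must be x/y/likelihood")
  body <- utils::type.convert(raw[-(1:3), -1, drop = FALSE], as.is = TRUE)
  n <- nrow(body)
  parts <- unique(parts_row)
  xy <- array(NA_real_, c(n, length(parts), 2L),
              dimnames = list(NULL, parts, c("x", "y")))
  conf <- matrix(1, n, length(parts), dimnames = list(NULL, parts))
  for (p in parts) {
    for (cc in c("x", "y")) {
      j <- which(parts_row == p & coords_row == cc)
      if (length(j) != 1L) stop("malformed keypoint CSV: bodypart ", p)
      xy[, p, cc] <- as.numeric(body[[j]])
    }
    j <- which(parts_row == p & coords_row == "likelihood")
    if (length(j) == 1L) conf[, p] <- as.numeric(body[[j]])
  }
  interp <- interpolate_low_confidence(xy, conf, min_confidence)
  keypoint_track(interp$xy, conf, fps = fps, px_per_mm = px_per_mm,
                 interpolated = interp$spans)
}

interpolate_low_confidence <- function(xy, conf, min_confidence) {
  spans <- list()
  n <- nrow(conf)
  for (p in colnames(conf)) {
    bad <- conf[, p] < min_confidence
    if (!any(bad) || all(bad)) next
    good <- which(!bad)
    for (cc in c("x", "y")) {
      xy[bad, p, cc] <- stats::approx(good, xy[good, p, cc],
                                      xout = which(bad), rule = 2)$y
    }
    r <- rle(bad)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    spans[[p]] <- cbind(start = starts[r$values], end = ends[r$values])
  }
  list(xy = xy, spans = spans)
}

#' Write a keypoint track in the three-header-row CSV dialect
#'
#' @param track A `keypoint_track`.
#' @param path Output path.
#' @param scorer Scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(track, path, scorer = "ovipost") {
  parts <- dimnames(track$xy)[[2]]
  n <- dim(track$xy)[1]
  header1 <- c("scorer", rep(scorer, 3L * length(parts)))
  header2 <- c("bodyparts", rep(parts, each = 3L))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  body <- matrix(0, n, 3L * length(parts))
  for (i in seq_along(parts)) {
    body[, 3L * i - 2L] <- track$xy[, i, "x"]
    body[, 3L * i - 1L] <- track$xy[, i, "y"]
    body[, 3L * i] <- track$confidence[, i]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(cbind(seq_len(n) - 1L, body), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}
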