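# Frame-to-frame linking of detections into longitudinal aggregate tracks.
#
# Assignment per frame pair is greedy on ascending displacement (ties broken
# by lowest track id), gated by a maximum per-step displacement; unmatched
# detections seed new tracks; tracks survive a bounded number of missed
# frames and then close. A track whose nearest detection was claimed by
# another track is recorded as merging into the claimant (small aggregates
# occasionally merge into larger ones).

link_defaults <- function() {
  list(d_max = 15,     # max displacement (px) per frame step
       gap_max = 2,    # frames a track may go undetected before closing
       min_length = 2) # min detections per track (1 keeps single-frame ones)
}

#' Link detections into aggregate tracks
#'
#' @param detections Data frame from [detect_series()] (columns `frame`,
#'   `x`, `y`, at least), sorted by frame.
#' @param link_config Named list overriding `aggflux:::link_defaults()`.
#' @return An object of class `agg_tracks`: list with `detections` (the
#'   input rows plus `track_id` and `event`), `merges` (data frame: `frame`,
#'   `track_id`, `into_track_id`), and `config`. Track ids are assigned in
#'   order of first appearance.
#' @export
link_tracks <- function(detections, link_config = list()) {
  cfg <- merge_config(link_defaults(), link_config)
  if (cfg$d_max <= 0) stop("d_max must be > 0")
  det <- detections
  merges <- data.frame(frame = integer(), track_id = integer(),
                       into_track_id = integer())
  if (nrow(det) == 0) {
    det$track_id <- integer(0)
    det$event <- character(0)
    return(structure(list(detections = det, merges = merges, config = cfg),
                     class = "agg_tracks"))
  }
  if (is.unsorted(det$frame)) stop("detections must be sorted by frame")
  det$track_id <- NA_integer_
  det$event <- ""
  # active track state
  act_id <- integer(); act_x <- numeric(); act_y <- numeric()
  act_frame <- integer()
  next_id <- 1L
  frames <- sort(unique(det$frame))
  for (f in frames) {
    rows <- which(det$frame == f)
    # drop tracks whose gap exceeded gap_max
    keep <- f - act_frame <= cfg$gap_max + 1L
    act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
    act_frame <- act_frame[keep]
    n_a <- length(act_id); n_d <- length(rows)
    assigned_det <- rep(NA_integer_, n_d)   # index into active tracks
    if (n_a && n_d) {
      dx <- outer(act_x, det$x[rows], "-")
      dy <- outer(act_y, det$y[rows], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= cfg$d_max, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], act_id[cand[, 1]])
        used_a <- logical(n_a); used_d <- logical(n_d)
        for (k in ord) {
          a <- cand[k, 1]; dd <- cand[k, 2]
          if (used_a[a] || used_d[dd]) next
          used_a[a] <- TRUE; used_d[dd] <- TRUE
          assigned_det[dd] <- a
        }
      }
    }
    for (dd in seq_len(n_d)) {
      r <- rows[dd]
      if (is.na(assigned_det[dd])) {
        det$track_id[r] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, det$x[r]); act_y <- c(act_y, det$y[r])
        act_frame <- c(act_frame, f)
        next_id <- next_id + 1L
      } else {
        a <- assigned_det[dd]
        det$track_id[r] <- act_id[a]
        act_x[a] <- det$x[r]; act_y[a] <- det$y[r]
        act_frame[a] <- f
      }
    }
    # merge bookkeeping: an unmatched active track (seen last frame) whose
    # nearest current detection lies within d_max merged into that track
    if (n_a && n_d) {
      for (a in seq_len(n_a)) {
        if (a %in% assigned_det) next
        if (act_frame[a] != f - 1L) next
        d2 <- (det$x[rows] - act_x[a])^2 + (det$y[rows] - act_y[a])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) <= cfg$d_max) {
          merges <- rbind(merges, data.frame(
            frame = f, track_id = act_id[a],
            into_track_id = det$track_id[rows[j]]))
          act_frame[a] <- -1000L  # force closure
        }
      }
    }
  }
  if (cfg$min_length > 1 && nrow(det)) {
    n_per <- table(det$track_id)
    short <- as.integer(names(n_per)[n_per < cfg$min_length])
    det <- det[!det$track_id %in% short, , drop = FALSE]
    merges <- merges[!merges$track_id %in% short &
                     !merges$into_track_id %in% short, , drop = FALSE]
  }
  structure(list(detections = det, merges = merges, config = cfg),
            class = "agg_tracks")
}

#' @export
print.agg_tracks <- function(x, ...) {
  cat(sprintf("<agg_tracks> %d track(s), %d detection row(s), %d merge event(s)\n",
              length(unique(x$detections$track_id)), nrow(x$detections),
              nrow(x$merges)))
  invisible(x)
}

#' Detection precision/recall against ground truth
#'
#' Matches detections to ground-truth aggregate positions per frame
#' (greedy nearest within `radius`, only aggregates whose fluorescence is at
#' least `min_fluor`) and reports precision, recall and F1.
#'
#' @param detections Data frame with `frame`, `x`, `y`.
#' @param truth Ground-truth aggregate table from [render_series()].
#' @param radius Match radius (px), default 2.
#' @param min_fluor Minimum ground-truth fluorescent amount for an aggregate
#'   to count as detectable (default 0: all).
#' @return List with `precision`, `recall`, `f1`, `n_matched`, `n_det`,
#'   `n_truth`.
#' @export
detection_prf <- function(detections, truth, radius = 2, min_fluor = 0) {
  tr <- truth[truth$fluor_total >= min_fluor, ]
  n_match <- 0L
  for (f in unique(c(detections$frame, tr$frame))) {
    d <- detections[detections$frame == f, ]
    g <- tr[tr$frame == f, ]
    if (!nrow(d) || !nrow(g)) next
    dist <- sqrt(outer(d$x, g$x, "-")^2 + outer(d$y, g$y, "-")^2)
    cand <- which(dist <= radius, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(dist[cand])
    used_d <- logical(nrow(d)); used_g <- logical(nrow(g))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_d[i] || used_g[j]) next
      used_d[i] <- TRUE; used_g[j] <- TRUE
      n_match <- n_match + 1L
    }
  }
  precision <- if (nrow(detections)) n_match / nrow(detections) else NA_real_
  recall <- if (nrow(tr)) n_match / nrow(tr) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = n_match, n_det = nrow(detections), n_truth = nrow(tr))
}

#' Track identity fraction against ground truth
#'
#' Assigns each tracked detection to the nearest ground-truth aggregate
#' within `radius` (per frame); each track's identity is the majority truth
#' id over its matched frames. The identity fraction is the proportion of
#' matched frames attributed to their track's majority id.
#'
#' @inheritParams detection_prf
#' @param tracks An `agg_tracks` object.
#' @return List with `identity_fraction`, `n_matched_frames`.
#' @export
track_identity <- function(tracks, truth, radius = 2) {
  det <- tracks$detections
  det$truth_id <- NA_integer_
  for (f in unique(det$frame)) {
    d <- which(det$frame == f)
    g <- truth[truth$frame == f, ]
    if (!length(d) || !nrow(g)) next
    dist <- sqrt(outer(det$x[d], g$x, "-")^2 + outer(det$y[d], g$y, "-")^2)
    cand <- which(dist <= radius, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(dist[cand])
    used_d <- logical(length(d)); used_g <- logical(nrow(g))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_d[i] || used_g[j]) next
      used_d[i] <- TRUE; used_g[j] <- TRUE
      det$truth_id[d[i]] <- g$aggregate_id[j]
    }
  }
  m <- det[!is.na(det$truth_id), ]
  if (!nrow(m)) return(list(identity_fraction = NA_real_,
                            n_matched_frames = 0L))
  ok <- 0L
  for (id in unique(m$track_id)) {
    ids <- m$truth_id[m$track_id == id]
    maj <- as.integer(names(which.max(table(ids))))
    ok <- ok + sum(ids == maj)
  }
  list(identity_fraction = ok / nrow(m), n_matched_frames = nrow(m))
}
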