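# Compartment assignment of tracked aggregates: nucleus / soma / axon /
# dendrite / unresolved, using every frame of a track (forward and backward
# in time) against the morphology reference.

assign_defaults <- function() {
  list(
    d_assign = 3,        # max distance (px) to a skeleton for attribution
    f_min = 0.6,         # required support fraction among evidence frames
    z_tol = 2,           # max |z_best - soma plane| for nuclear/somatic calls
    visibility = "auto") # numeric floor, or "auto": median + 2 MAD of the
                         # morphology projection; NULL disables the check
}

COMPARTMENT_PRIORITY <- c("nucleus", "soma", "axon", "dendrite")

#' Assign a neuronal compartment to one aggregate track
#'
#' For every frame of the track: the aggregate is attributed to the nucleus
#' if its position falls inside the nucleus mask at a best-focus plane near
#' the soma's plane, else to the soma under the same rule, else to the
#' nearest axon or dendrite skeleton within `d_assign` pixels whose local
#' morphology intensity exceeds the visibility floor. The final label is the
#' majority over frames with evidence and must be supported by at least
#' `f_min` of them, otherwise the track is `unresolved`. The vote is
#' invariant under frame-order reversal. With invisible axons (morphology
#' below the floor) axon-hosted aggregates become unresolved rather than
#' being attributed to another structure.
#'
#' @param track Data frame of one track's detections (`frame`, `x`, `y`,
#'   `z_best`), or an `agg_tracks` object together with `track_id`.
#' @param geom A [make_geometry()] object (masks and skeletons are inputs).
#' @param morph_proj Optional Y x X morphology projection used for the
#'   visibility floor; `NULL` skips the visibility check.
#' @param assign_config Named list overriding
#'   `aggflux:::assign_defaults()`.
#' @param track_id Track id when `track` is an `agg_tracks` object.
#'
#' @return A list of class `compartment_call`: `track_id`, `label`,
#'   `confidence` (support fraction among evidence frames),
#'   `n_frames_evidence`, and `evidence` (per-frame data frame: `frame`,
#'   `structure`, `dist`, `morph_int`).
#' @export
assign_compartment <- function(track, geom, morph_proj = NULL,
                               assign_config = list(), track_id = NULL) {
  cfg <- merge_config(assign_defaults(), assign_config)
  if (inherits(track, "agg_tracks")) {
    if (is.null(track_id)) stop("track_id required with an agg_tracks input")
    track <- track$detections[track$detections$track_id == track_id, ]
  }
  id <- if (!is.null(track_id)) track_id
        else if (!is.null(track$track_id) && nrow(track)) track$track_id[1]
        else NA_integer_
  if (nrow(track) == 0) stop("track has zero detections")

  floor_val <- -Inf
  if (!is.null(morph_proj) && !is.null(cfg$visibility)) {
    floor_val <- if (identical(cfg$visibility, "auto")) {
      stats::median(morph_proj) + 2 * stats::mad(morph_proj)
    } else cfg$visibility
  }
  # local morphology level: 3x3 mean (a single noisy pixel must not decide
  # visibility)
  morph_at <- function(x, y) {
    if (is.null(morph_proj)) return(Inf)
    r <- max(1, min(nrow(morph_proj), round(y) + 1L))
    cl <- max(1, min(ncol(morph_proj), round(x) + 1L))
    rs <- max(1, r - 1):min(nrow(morph_proj), r + 1)
    cs <- max(1, cl - 1):min(ncol(morph_proj), cl + 1)
    mean(morph_proj[rs, cs])
  }
  # flattened skeleton point cloud
  sk_pts <- NULL
  if (length(geom$skeletons)) {
    sk_pts <- do.call(rbind, lapply(geom$skeletons, function(s) {
      cbind(s$pts, comp = match(s$compartment, COMPARTMENT_PRIORITY),
            skel = s$id)
    }))
  }
  in_mask <- function(mask, x, y) {
    r <- round(y) + 1L; cl <- round(x) + 1L
    r >= 1 && r <= nrow(mask) && cl >= 1 && cl <= ncol(mask) && mask[r, cl]
  }

  n <- nrow(track)
  structure_v <- character(n); dist_v <- rep(NA_real_, n)
  morph_v <- rep(NA_real_, n)
  have_soma <- nrow(geom$somas) > 0
  for (i in seq_len(n)) {
    x <- track$x[i]; y <- track$y[i]
    zb <- if (!is.null(track$z_best)) track$z_best[i] else NA
    structure_v[i] <- ""
    if (have_soma) {
      d2 <- (geom$somas$cx - x)^2 + (geom$somas$cy - y)^2
      z_soma <- geom$somas$z_soma[which.min(d2)]
      z_ok <- is.na(zb) || abs(zb - z_soma) <= cfg$z_tol
      if (z_ok && in_mask(geom$nucleus_mask, x, y)) {
        structure_v[i] <- "nucleus"; dist_v[i] <- 0
        morph_v[i] <- morph_at(x, y)
        next
      }
      if (z_ok && in_mask(geom$soma_mask, x, y)) {
        structure_v[i] <- "soma"; dist_v[i] <- 0
        morph_v[i] <- morph_at(x, y)
        next
      }
    }
    if (!is.null(sk_pts)) {
      d2 <- (sk_pts[, 1] - x)^2 + (sk_pts[, 2] - y)^2
      near <- which(d2 <= cfg$d_assign^2)
      if (length(near)) {
        # one candidate point per skeleton (its nearest), tried in order
        # of distance: the nearest *visible* structure wins
        skels <- unique(sk_pts[near, "skel"])
        cand <- vapply(skels, function(s) {
          jj <- near[sk_pts[near, "skel"] == s]
          jj[which.min(d2[jj])]
        }, 0)
        for (j in cand[order(d2[cand])]) {
          mi <- morph_at(sk_pts[j, 1], sk_pts[j, 2])
          if (mi >= floor_val) {
            structure_v[i] <- COMPARTMENT_PRIORITY[sk_pts[j, "comp"]]
            dist_v[i] <- sqrt(d2[j]); morph_v[i] <- mi
            break
          }
        }
      }
    }
  }
  evid <- structure_v != ""
  n_evid <- sum(evid)
  if (n_evid == 0) {
    label <- "unresolved"; conf <- 0
  } else {
    votes <- table(factor(structure_v[evid], levels = COMPARTMENT_PRIORITY))
    best <- COMPARTMENT_PRIORITY[which.max(votes)]  # ties: fixed priority
    conf <- max(votes) / n_evid
    # a structure must support the call in >= f_min of ALL frames: a
    # transient proximity (an aggregate brushing past a dendrite) is not a
    # localization
    label <- if (conf >= cfg$f_min && max(votes) / n >= cfg$f_min) best
             else "unresolved"
  }
  structure(
    list(track_id = id, label = label, confidence = as.numeric(conf),
         n_frames_evidence = n_evid,
         evidence = data.frame(frame = track$frame,
                               structure = structure_v, dist = dist_v,
                               morph_int = morph_v,
                               stringsAsFactors = FALSE)),
    class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  cat(sprintf("<compartment_call> track %s -> %s (confidence %.2f, %d evidence frame(s))\n",
              as.character(x$track_id), x$label, x$confidence,
              x$n_frames_evidence))
  invisible(x)
}

#' Assign compartments to all tracks
#'
#' @param tracks An `agg_tracks` object.
#' @param geom A [make_geometry()] object.
#' @param morph_proj Optional morphology projection (see
#'   [assign_compartment()]).
#' @param assign_config See [assign_compartment()].
#' @return Data frame: `track_id`, `label`, `confidence`,
#'   `n_frames_evidence`.
#' @export
assign_compartments <- function(tracks, geom, morph_proj = NULL,
                                assign_config = list()) {
  ids <- sort(unique(tracks$detections$track_id))
  rows <- lapply(ids, function(id) {
    cl <- assign_compartment(tracks, geom, morph_proj, assign_config,
                             track_id = id)
    data.frame(track_id = id, label = cl$label, confidence = cl$confidence,
               n_frames_evidence = cl$n_frames_evidence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
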