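# Trace-level readouts: ROI means, cytosolic means, t = 0 normalization,
# per-FOV aggregate-count curves.
#
# Image convention used throughout the package: a single-channel image is a
# Y x X matrix; continuous coordinates are 0-based with pixel centers at
# integers, so coordinate (x, y) refers to matrix element [y + 1, x + 1].

#' Intensity trace
#'
#' @param times Time points (h).
#' @param values Intensities (a.u.), same length as `times`.
#' @param subject Identifier of the traced object (track id or cytosol ROI id).
#' @param channel Channel name.
#' @param normalized Whether the trace has been divided by its first value.
#' @param reference_value The divisor stored by [normalize_trace()].
#' @return An object of class `agg_trace`.
#' @export
new_trace <- function(times, values, subject = NA, channel = NA,
                      normalized = FALSE, reference_value = NA_real_) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) > 1 && is.unsorted(times)) stop("times must be increasing")
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         subject = subject, channel = channel, normalized = normalized,
         reference_value = reference_value),
    class = "agg_trace")
}

#' @export
print.agg_trace <- function(x, ...) {
  cat(sprintf("<agg_trace> subject=%s channel=%s n=%d%s\n",
              as.character(x$subject), as.character(x$channel),
              length(x$times), if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @export
as.data.frame.agg_trace <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(subject = as.character(x$subject),
             channel = as.character(x$channel),
             time_h = x$times, value = x$values,
             normalized = x$normalized, stringsAsFactors = FALSE)
}

#' Normalize a trace to its first value
#'
#' Divides every value by the value at the first time point, storing that
#' value as `reference_value`. Normalizing an already-normalized trace is an
#' error (guarded: never a silent double division), as is a first value at or
#' below `eps`.
#'
#' @param trace An [new_trace()] object.
#' @param eps Smallest admissible first value (default 1e-6).
#' @return The normalized trace; its first value is exactly 1.
#' @export
normalize_trace <- function(trace, eps = 1e-6) {
  stopifnot(inherits(trace, "agg_trace"))
  if (trace$normalized) stop("trace is already normalized")
  if (length(trace$values) == 0) stop("empty trace")
  ref <- trace$values[1]
  if (!is.finite(ref) || ref <= eps) {
    stop(sprintf("cannot normalize: first value (%.3g) <= eps (%.3g)",
                 ref, eps))
  }
  trace$values <- trace$values / ref
  trace$values[1] <- 1  # exact by contract
  trace$normalized <- TRUE
  trace$reference_value <- ref
  trace
}

# pixel-center grid of a disk ROI; returns matrix indices (may be empty)
disk_pixels <- function(dim_yx, center_xy, radius) {
  x0 <- center_xy[1]; y0 <- center_xy[2]
  xs <- seq(max(0, floor(x0 - radius)), min(dim_yx[2] - 1, ceiling(x0 + radius)))
  ys <- seq(max(0, floor(y0 - radius)), min(dim_yx[1] - 1, ceiling(y0 + radius)))
  if (!length(xs) || !length(ys) || min(xs) > dim_yx[2] - 1 || min(ys) > dim_yx[1] - 1) {
    return(cbind(row = integer(), col = integer()))
  }
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - x0)^2 + (g$y - y0)^2 <= radius^2
  cbind(row = g$y[keep] + 1L, col = g$x[keep] + 1L)
}

#' Mean intensity in a disk ROI
#'
#' Mean over pixels whose centers lie within the disk of given radius around
#' `center` (0-based continuous coordinates). A radius of 0 returns the value
#' of the pixel whose center is nearest.
#'
#' @param projection Y x X numeric matrix (typically a maximal-intensity
#'   projection).
#' @param center Numeric `c(x, y)`.
#' @param radius Disk radius (px).
#' @return Mean intensity (a.u.). Errors if the ROI lies entirely outside the
#'   image.
#' @export
measure_roi <- function(projection, center, radius) {
  stopifnot(is.matrix(projection), length(center) == 2, radius >= 0)
  if (radius == 0) {
    row <- round(center[2]) + 1L
    col <- round(center[1]) + 1L
    if (row < 1 || row > nrow(projection) || col < 1 || col > ncol(projection)) {
      stop("ROI entirely outside image")
    }
    return(projection[row, col])
  }
  px <- disk_pixels(dim(projection), center, radius)
  if (nrow(px) == 0) stop("ROI entirely outside image")
  mean(projection[px])
}

#' Background-subtracted punctum intensity
#'
#' Classic punctum photometry: the mean over the central disk minus the
#' mean over a surrounding annulus. The annulus captures the local ambient
#' level (diffuse cytosolic fluorescence, camera offset) so the returned
#' value reflects the punctum's own signal; it can be slightly negative on
#' empty positions.
#'
#' @inheritParams measure_roi
#' @param bg_in,bg_out Inner and outer radii (px) of the background
#'   annulus; defaults `radius + 1` and `radius + 4`.
#' @return Disk mean minus annulus mean (a.u.).
#' @export
measure_punctum <- function(projection, center, radius, bg_in = radius + 1,
                            bg_out = radius + 4) {
  stopifnot(bg_out > bg_in, bg_in >= radius)
  inner <- disk_pixels(dim(projection), center, radius)
  outer_px <- disk_pixels(dim(projection), center, bg_out)
  if (nrow(inner) == 0 || nrow(outer_px) == 0) {
    stop("ROI entirely outside image")
  }
  ex <- disk_pixels(dim(projection), center, bg_in)
  key <- function(m) paste(m[, 1], m[, 2])
  ann <- outer_px[!key(outer_px) %in% key(ex), , drop = FALSE]
  if (nrow(ann) == 0) stop("background annulus entirely outside image")
  mean(projection[inner]) - mean(projection[ann])
}

#' Mean cytosolic intensity over a mask, excluding aggregate footprints
#'
#' Computes the mean intensity over `region_mask` after removing a disk of
#' radius `roi_radius + dilate_px` around every supplied detection (the
#' dilation guards against punctum bleed-through). The same mask is intended
#' to be reused across all frames of a series, mirroring a manually placed
#' first-frame ROI.
#'
#' @param projection Y x X numeric matrix.
#' @param region_mask Y x X logical matrix (the manual ROI).
#' @param detections Data frame with columns `x`, `y` (0-based), or `NULL`.
#' @param roi_radius Footprint radius per detection (px), default 4.
#' @param dilate_px Extra dilation of each footprint (px), default 2.
#' @return Mean intensity (a.u.). Errors if the mask is empty or the
#'   exclusion empties it.
#' @export
measure_cytosol <- function(projection, region_mask, detections = NULL,
                            roi_radius = 4, dilate_px = 2) {
  stopifnot(is.matrix(projection), is.logical(region_mask),
            all(dim(projection) == dim(region_mask)))
  if (!any(region_mask)) stop("region mask is empty")
  keep <- region_mask
  if (!is.null(detections) && nrow(detections) > 0) {
    r <- roi_radius + dilate_px
    for (i in seq_len(nrow(detections))) {
      px <- disk_pixels(dim(projection),
                        c(detections$x[i], detections$y[i]), r)
      if (nrow(px)) keep[px] <- FALSE
    }
  }
  if (!any(keep)) stop("aggregate exclusion emptied the cytosol mask")
  mean(projection[keep])
}

#' Per-FOV aggregate count curve
#'
#' Counts, at each requested time, the tracks having a detection at that time
#' or being inside an open gap (i.e. the time lies between the track's first
#' and last detected frames).
#'
#' @param tracks An `agg_tracks` object (see [link_tracks()]) or its
#'   detections data frame (columns `track_id`, `time_h`).
#' @param times Times (h) at which to count.
#' @return An object of class `count_curve`: data frame with `time_h` and
#'   integer `count`.
#' @export
count_curve <- function(tracks, times) {
  det <- if (inherits(tracks, "agg_tracks")) tracks$detections else tracks
  counts <- integer(length(times))
  if (!is.null(det) && nrow(det) > 0) {
    rng <- tapply(det$time_h, det$track_id, range)
    lo <- vapply(rng, `[`, numeric(1), 1)
    hi <- vapply(rng, `[`, numeric(1), 2)
    for (k in seq_along(times)) {
      counts[k] <- sum(lo <= times[k] + 1e-9 & hi >= times[k] - 1e-9)
    }
  }
  out <- data.frame(time_h = times, count = counts)
  class(out) <- c("count_curve", "data.frame")
  out
}
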