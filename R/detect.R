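# Punctum detection on maximal-intensity projections: band-pass
# (difference-of-Gaussians) filtering, MAD-robust thresholding, local
# maxima with sub-pixel refinement. Identical parameters are applied to
# every frame of a series.

detect_defaults <- function() {
  list(
    sigma_spot = 1.3,   # punctum scale (px) of the band-pass filter
    k_mad = 100,        # candidate threshold: median + k_mad * MAD (band-pass)
                        # (the MAD of a band-passed max projection reflects
                        # dark-background noise; shot noise and clutter on
                        # cytosol-filled structures — neurite crossings,
                        # bright somata — sit an order of magnitude higher)
    k_local = 8,        # peak >= local median + k_local * local MAD (raw)
    local_w = 7,        # half-width (px) of the local background window
    blob_ratio = 0.35,  # min |Hessian eigenvalue| ratio (rejects ridges)
    min_area = 3,       # px^2 of connected band-pass response per spot
    min_sep = 3,        # px minimum separation between detections
    border = 3,         # px margin: maxima this close to the edge are
                        # dropped (filter edge effects, truncated objects)
    exclude_mask = NULL)# optional Y x X logical: suppress detections inside
}

#' Maximal-intensity projection
#'
#' Per-pixel maximum over the z dimension.
#'
#' @param stack One frame as a C x Z x Y x X (4-d) or Z x Y x X (3-d) array.
#' @return C x Y x X array, or Y x X matrix for 3-d input. Errors on an
#'   empty stack.
#' @export
max_project <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || !length(stack)) stop("empty stack")
  if (length(d) == 3) {
    out <- stack[1, , ]
    for (z in seq_len(d[1])[-1]) out <- pmax(out, stack[z, , ])
    return(out)
  }
  if (length(d) != 4) stop("stack must be C x Z x Y x X or Z x Y x X")
  if (d[2] < 1) stop("empty stack")
  out <- array(0, dim = d[c(1, 3, 4)])
  for (ci in seq_len(d[1])) {
    m <- stack[ci, 1, , ]
    for (z in seq_len(d[2])[-1]) m <- pmax(m, stack[ci, z, , ])
    out[ci, , ] <- m
  }
  out
}

# 3x3 maximum filter via shifted copies (replicated borders)
max_filter3 <- function(m) {
  Y <- nrow(m); X <- ncol(m)
  up <- m[c(1, seq_len(Y - 1)), ]; dn <- m[c(seq_len(Y - 1) + 1, Y), ]
  out <- pmax(m, up, dn)
  out <- pmax(out, out[, c(1, seq_len(X - 1))], out[, c(seq_len(X - 1) + 1, X)])
  out
}

# parabolic sub-pixel offset from three samples; clamped to [-0.5, 0.5]
parabolic_offset <- function(vm, v0, vp) {
  den <- vm - 2 * v0 + vp
  if (den >= 0) return(0)  # not a local max along this axis
  max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
}

#' Detect fluorescent puncta in a single projection
#'
#' Band-pass filters the image at the punctum scale (difference of
#' Gaussians) and finds local maxima above `median + k_mad * MAD` of the
#' filtered image. Each candidate must then (i) exceed its local raw
#' background by `k_local` local MADs (robust signal-to-noise against shot
#' noise on bright structures), and (ii) be blob-shaped: the ratio of the
#' band-pass Hessian eigenvalue magnitudes at the maximum must reach
#' `blob_ratio`, which rejects ridge responses along cytosol-filled
#' neurites. A minimum connected response area and a minimum separation are
#' enforced and positions are refined to sub-pixel precision by parabolic
#' interpolation.
#'
#' @param image Y x X numeric matrix (a maximal-intensity projection).
#' @param det_config Named list overriding `aggflux:::detect_defaults()`.
#' @return Data frame with columns `x`, `y` (0-based, continuous), `peak`
#'   (raw image value at the maximum), `area` (px of connected band-pass
#'   response), `response` (band-pass value). Errors on non-finite pixels.
#' @export
detect_spots <- function(image, det_config = list()) {
  cfg <- merge_config(detect_defaults(), det_config)
  if (!is.matrix(image)) stop("image must be a Y x X matrix")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  bp <- EBImage::gblur(image, sigma = cfg$sigma_spot) -
        EBImage::gblur(image, sigma = 2 * cfg$sigma_spot)
  thr <- stats::median(bp) + cfg$k_mad * stats::mad(bp)
  above <- bp > thr
  if (!is.null(cfg$exclude_mask)) above <- above & !cfg$exclude_mask
  is_max <- (bp == max_filter3(bp)) & above
  b <- max(1L, as.integer(cfg$border))
  is_max[c(seq_len(b), nrow(bp) - seq_len(b) + 1L), ] <- FALSE
  is_max[, c(seq_len(b), ncol(bp) - seq_len(b) + 1L)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x = numeric(), y = numeric(), peak = numeric(),
                      area = numeric(), response = numeric()))
  }
  comp <- EBImage::bwlabel(above)
  areas <- tabulate(comp[comp > 0])
  keep <- areas[comp[idx]] >= cfg$min_area
  # local raw-background criterion and blobness criterion
  Y <- nrow(image); X <- ncol(image)
  w <- cfg$local_w
  for (i in which(keep)) {
    r <- idx[i, 1]; cl <- idx[i, 2]
    win <- image[max(1, r - w):min(Y, r + w), max(1, cl - w):min(X, cl + w)]
    bg <- stats::median(win)
    s <- stats::mad(win)
    if (s <= 0) s <- sqrt(max(bg, 1))  # shot-noise floor on flat windows
    if (image[r, cl] - bg < cfg$k_local * s) { keep[i] <- FALSE; next }
    if (r > 1 && r < Y && cl > 1 && cl < X) {
      hxx <- bp[r, cl - 1] - 2 * bp[r, cl] + bp[r, cl + 1]
      hyy <- bp[r - 1, cl] - 2 * bp[r, cl] + bp[r + 1, cl]
      hxy <- (bp[r + 1, cl + 1] - bp[r + 1, cl - 1] -
              bp[r - 1, cl + 1] + bp[r - 1, cl - 1]) / 4
      disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
      l1 <- (hxx + hyy) / 2 - disc
      l2 <- (hxx + hyy) / 2 + disc
      if (l2 >= 0 || abs(l2) < cfg$blob_ratio * abs(l1)) keep[i] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  if (!nrow(idx)) {
    return(data.frame(x = numeric(), y = numeric(), peak = numeric(),
                      area = numeric(), response = numeric()))
  }
  # order by decreasing response; greedily enforce min separation
  ord <- order(bp[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  kept <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    prev <- idx[kept, , drop = FALSE]
    d2 <- (prev[, 1] - idx[i, 1])^2 + (prev[, 2] - idx[i, 2])^2
    if (all(d2 >= cfg$min_sep^2)) kept[i] <- TRUE
  }
  idx <- idx[kept, , drop = FALSE]
  out <- data.frame(x = numeric(nrow(idx)), y = numeric(nrow(idx)),
                    peak = numeric(nrow(idx)), area = numeric(nrow(idx)),
                    response = numeric(nrow(idx)))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cl <- idx[i, 2]
    dy <- parabolic_offset(bp[r - 1, cl], bp[r, cl], bp[r + 1, cl])
    dx <- parabolic_offset(bp[r, cl - 1], bp[r, cl], bp[r, cl + 1])
    out$x[i] <- (cl - 1) + dx
    out$y[i] <- (r - 1) + dy
    out$peak[i] <- image[r, cl]
    out$area[i] <- areas[comp[r, cl]]
    out$response[i] <- bp[r, cl]
  }
  out[order(out$y, out$x), , drop = FALSE]
}

#' Detect puncta across all frames of a series
#'
#' Applies [max_project()] and [detect_spots()] with identical parameters to
#' every frame of one channel, adding the best-focus plane (arg max over z
#' at the detection pixel).
#'
#' @param series An `image_series` or `lazy_series`.
#' @param channel Channel name to detect in.
#' @param det_config See [detect_spots()].
#' @param frames Frame indices (default: all).
#' @return Data frame: `frame`, `time_h`, `channel`, `x`, `y`, `z_best`,
#'   `peak`, `area`, `response`.
#' @export
detect_series <- function(series, channel, det_config = list(),
                          frames = NULL) {
  ci <- match(channel, series$channel_names)
  if (is.na(ci)) {
    stop("channel '", channel, "' not in series (",
         paste(series$channel_names, collapse = ", "), ")")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(series))
  times <- frame_times(series)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    fr <- get_frame(series, t)             # C x Z x Y x X
    stack <- array(fr[ci, , , ], dim = dim(fr)[2:4])
    proj <- max_project(stack)
    det <- detect_spots(proj, det_config)
    if (nrow(det)) {
      zb <- integer(nrow(det))
      for (i in seq_len(nrow(det))) {
        zb[i] <- which.max(stack[, round(det$y[i]) + 1L,
                                 round(det$x[i]) + 1L]) - 1L
      }
      det$z_best <- zb
      det$frame <- t
      det$time_h <- times[t]
      det$channel <- channel
    }
    out[[k]] <- det
  }
  out <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  if (is.null(out)) {
    out <- data.frame(x = numeric(), y = numeric(), peak = numeric(),
                      area = numeric(), response = numeric(),
                      z_best = integer(), frame = integer(),
                      time_h = numeric(), channel = character())
  }
  rownames(out) <- NULL
  out[, c("frame", "time_h", "channel", "x", "y", "z_best", "peak", "area",
          "response")]
}
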