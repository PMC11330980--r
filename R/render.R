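# Rendering of kinetic trajectories into multi-channel, multi-z, noisy
# 12-bit time-lapse image series with paired ground truth.
#
# Images are rendered per z-plane: a compartment-filling cytosolic component
# proportional to the fluorescent cytosolic amount, plus one 3-D Gaussian
# punctum per aggregate whose integrated intensity is proportional to its
# fluorescent bound amount. Signal then receives Poisson shot noise and
# Gaussian read noise and is clipped/quantized to the 12-bit range.

MAX_DN <- 4095  # 12-bit full scale

optics_defaults <- function() {
  list(
    sigma_xy = 1.3,         # punctum lateral sd (px)
    sigma_z = 1.0,          # punctum axial sd (planes)
    gain_agg = 12000,       # counts per a.u. of bound fluorescent amount
    gain_cyt = 4,           # counts/px per a.u. of cytosolic amount
    gain_morph = 1000,      # counts/px at unit morphology weight
    axon_visibility = 0.1,  # morphology weight of axons vs dendrites
    axon_cyt_weight = 0.35, # partial-volume cytosol weight of thin axons
    nucleus_cyt_weight = 1, # reporter enters nuclei freely
    bg_offset = 20,         # counts of ambient background light
    read_sd = 1.5,          # Gaussian read noise sd (counts)
    poisson = TRUE,
    quantize = TRUE,
    motion_step = 2,        # aggregate random-walk step sd (px/frame)
    min_spacing = 0,        # min initial distance (px) between aggregates
    soma_z_sd = 1.5)        # soma z-extent (planes, Gaussian)
}

# stamp value*weight discs of radius r along dense points into mat (max
# rule); `taper` linearly shrinks radius and weight over the final fraction
# of the polyline (neurites thin toward their tips; without tapering a
# rasterized end cap is a punctum-sized blob artifact)
stamp_points <- function(mat, pts, r, value, taper = 0) {
  Y <- nrow(mat); X <- ncol(mat)
  n <- nrow(pts)
  scale <- rep(1, n)
  if (taper > 0 && n > 1) {
    i0 <- ceiling(n * (1 - taper))
    ramp <- seq(1, 0.15, length.out = n - i0 + 1L)
    scale[i0:n] <- ramp
  }
  for (i in seq_len(n)) {
    px <- disk_pixels(c(Y, X), pts[i, ], max(0.4, r * scale[i]))
    if (nrow(px)) mat[px] <- pmax(mat[px], value * scale[i])
  }
  mat
}

# per-z weight maps for the morphology and cytosol components
build_weight_maps <- function(geom, optics) {
  Y <- geom$fov_shape[1]; X <- geom$fov_shape[2]
  nz <- geom$n_z
  zero <- matrix(0, Y, X)
  morph <- replicate(nz, zero, simplify = FALSE)
  cyt <- replicate(nz, zero, simplify = FALSE)
  for (i in seq_len(nrow(geom$somas))) {
    s <- geom$somas[i, ]
    px <- disk_pixels(c(Y, X), c(s$cx, s$cy), s$r)
    for (z in seq_len(nz) - 1L) {
      wz <- exp(-(z - s$z_soma)^2 / (2 * optics$soma_z_sd^2))
      if (wz < 0.01) next
      morph[[z + 1L]][px] <- pmax(morph[[z + 1L]][px], wz)
      cyt[[z + 1L]][px] <- pmax(cyt[[z + 1L]][px], wz)
    }
  }
  for (sk in geom$skeletons) {
    tp <- if (sk$exits_fov) 0 else 0.25  # tips inside the FOV taper out
    if (sk$compartment == "dendrite") {
      zs <- intersect(sk$z_level + (-1:1), seq_len(geom$n_z) - 1L)
      for (z in zs) {
        wz <- if (z == sk$z_level) 1 else 0.5
        r <- geom$config$dendrite_width / 2
        morph[[z + 1L]] <- stamp_points(morph[[z + 1L]], sk$pts, r, wz, tp)
        cyt[[z + 1L]] <- stamp_points(cyt[[z + 1L]], sk$pts, r, wz, tp)
      }
    } else {
      z <- sk$z_level
      r <- max(0.5, geom$config$axon_width / 2)
      morph[[z + 1L]] <- stamp_points(morph[[z + 1L]], sk$pts, r,
                                      optics$axon_visibility, tp)
      cyt[[z + 1L]] <- stamp_points(cyt[[z + 1L]], sk$pts, r,
                                    optics$axon_cyt_weight, tp)
    }
  }
  if (optics$nucleus_cyt_weight != 1 && any(geom$nucleus_mask)) {
    for (z in seq_len(nz)) {
      cyt[[z]][geom$nucleus_mask] <-
        cyt[[z]][geom$nucleus_mask] * optics$nucleus_cyt_weight
    }
  }
  list(morph = morph, cyt = cyt)
}

# sample per-aggregate positions for every recorded frame: skeleton-hosted
# aggregates perform a reflected random walk along their host polyline
place_aggregates <- function(traj, geom, optics, seed) {
  set.seed(seed)
  agg <- traj$agg
  n <- nrow(agg)
  nt <- length(traj$times)
  pos <- array(NA_real_, dim = c(n, nt, 3),
               dimnames = list(NULL, NULL, c("x", "y", "z")))
  if (n == 0) return(pos)
  comp <- vapply(geom$skeletons, `[[`, character(1), "compartment")
  host <- integer(n)
  init_xy <- matrix(NA_real_, n, 2)
  far_enough <- function(x, y) {
    ok <- is.na(init_xy[, 1]) |
      (init_xy[, 1] - x)^2 + (init_xy[, 2] - y)^2 >= optics$min_spacing^2
    all(ok)
  }
  for (i in seq_len(n)) {
    born <- agg$birth_time[i] <= traj$times + 1e-9
    if (!any(born)) next
    first <- which(born)[1]
    if (agg$compartment[i] %in% c("axon", "dendrite")) {
      cand <- which(comp == agg$compartment[i])
      if (!length(cand)) {
        stop("geometry has no ", agg$compartment[i],
             " skeleton to host aggregate ", agg$id[i])
      }
      lens <- vapply(cand, function(k) max(geom$skeletons[[k]]$cum), 0)
      for (try in 1:60) {
        k <- cand[sample.int(length(cand), 1, prob = lens)]
        sk <- geom$skeletons[[k]]
        L <- max(sk$cum)
        s <- stats::runif(1, 0, L)
        j0 <- which.min(abs(sk$cum - s))
        if (optics$min_spacing <= 0 ||
            far_enough(sk$pts[j0, 1], sk$pts[j0, 2])) break
      }
      host[i] <- k
      init_xy[i, ] <- sk$pts[j0, ]
      for (t in first:nt) {
        s <- s + stats::rnorm(1, 0, optics$motion_step)
        # reflect into [0, L]
        s <- abs(s); s <- L - abs(L - s)
        j <- which.min(abs(sk$cum - s))
        pos[i, t, ] <- c(sk$pts[j, 1], sk$pts[j, 2], sk$z_level)
      }
    } else {
      mask <- if (agg$compartment[i] == "nucleus") geom$nucleus_mask
              else geom$soma_mask & !geom$nucleus_mask
      if (!any(mask)) stop("geometry has no soma to host aggregate ",
                           agg$id[i])
      idx <- which(mask, arr.ind = TRUE)
      for (try in 1:60) {
        j <- sample.int(nrow(idx), 1)
        x0 <- idx[j, 2] - 1; y0 <- idx[j, 1] - 1
        if (optics$min_spacing <= 0 || far_enough(x0, y0)) break
      }
      init_xy[i, ] <- c(x0, y0)
      d2 <- (geom$somas$cx - x0)^2 + (geom$somas$cy - y0)^2
      z0 <- geom$somas$z_soma[which.min(d2)]
      for (t in first:nt) {
        pos[i, t, ] <- c(x0 + stats::rnorm(1, 0, 0.2),
                         y0 + stats::rnorm(1, 0, 0.2), z0)
      }
    }
  }
  attr(pos, "host") <- host
  pos
}

# add one 3-D Gaussian punctum (total integral = itot) into the list of
# z-plane matrices; returns list(planes, saturated_window_max)
add_punctum <- function(planes, x, y, z, itot, sigma_xy, sigma_z) {
  Y <- nrow(planes[[1]]); X <- ncol(planes[[1]])
  wr <- ceiling(3 * sigma_xy)
  xs <- max(0, floor(x - wr)):min(X - 1, ceiling(x + wr))
  ys <- max(0, floor(y - wr)):min(Y - 1, ceiling(y + wr))
  if (!length(xs) || !length(ys)) return(planes)
  gx <- exp(-(xs - x)^2 / (2 * sigma_xy^2))
  gy <- exp(-(ys - y)^2 / (2 * sigma_xy^2))
  patch <- outer(gy, gx) / (2 * pi * sigma_xy^2)
  for (zi in seq_along(planes) - 1L) {
    gz <- exp(-(zi - z)^2 / (2 * sigma_z^2)) / (sqrt(2 * pi) * sigma_z)
    if (gz * itot < 1e-3) next
    planes[[zi + 1L]][ys + 1L, xs + 1L] <-
      planes[[zi + 1L]][ys + 1L, xs + 1L] + itot * gz * patch
  }
  planes
}

apply_noise <- function(plane, optics) {
  v <- plane + optics$bg_offset
  if (optics$poisson) {
    v <- matrix(stats::rpois(length(v), pmax(v, 0)), nrow(v), ncol(v))
  }
  if (optics$read_sd > 0) {
    v <- v + matrix(stats::rnorm(length(v), 0, optics$read_sd),
                    nrow(v), ncol(v))
  }
  if (optics$quantize) {
    v <- round(pmin(pmax(v, 0), MAX_DN))
  }
  v
}

#' Image series container
#'
#' @param data Numeric array with dimensions T x C x Z x Y x X, values in
#'   the unsigned 12-bit range.
#' @param dt Frame interval (h).
#' @param z_step Z spacing (um).
#' @param channel_names Character vector of length C.
#' @param pixel_size Pixel size (um/px).
#' @param t0 Time of the first frame (h), default 0.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, dt, z_step, channel_names, pixel_size,
                         t0 = 0) {
  d <- dim(data)
  if (length(d) != 5) stop("data must be a T x C x Z x Y x X array")
  if (d[1] < 1) stop("T must be >= 1")
  if (d[2] != length(channel_names)) {
    stop("channel_names must match the channel dimension")
  }
  if (min(data) < 0 || max(data) > MAX_DN) {
    stop("values must lie in [0, ", MAX_DN, "]")
  }
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(
    list(data = data, dt = dt, z_step = z_step,
         channel_names = channel_names, pixel_size = pixel_size, t0 = t0),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> T=%d C=%d Z=%d Y=%d X=%d, dt=%.3g h, channels: %s\n",
              d[1], d[2], d[3], d[4], d[5], x$dt,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Number of frames of a series (eager or lazy)
#' @param series An `image_series` or `lazy_series`.
#' @export
n_frames <- function(series) {
  if (inherits(series, "lazy_series")) series$n_t else dim(series$data)[1]
}

#' Frame times of a series
#' @param series An `image_series` or `lazy_series`.
#' @export
frame_times <- function(series) {
  series$t0 + (seq_len(n_frames(series)) - 1) * series$dt
}

#' Extract one frame (C x Z x Y x X) from an eager or lazy series
#' @param series An `image_series` or `lazy_series`.
#' @param t Frame index (1-based).
#' @export
get_frame <- function(series, t) {
  if (inherits(series, "lazy_series")) {
    series$frame(t)
  } else {
    d <- dim(series$data)
    array(series$data[t, , , , ], dim = d[2:5])
  }
}

#' Render a kinetic trajectory into an image series with ground truth
#'
#' Every record time of `traj` becomes one frame. Aggregates are rendered as
#' 3-D Gaussian puncta (integral proportional to fluorescent bound amount)
#' that move along their host skeleton by a reflected random walk; the
#' cytosol is rendered as a compartment-filling component proportional to
#' the fluorescent cytosolic amount; the morphology channel is constant over
#' time. Per-frame noise uses a seed derived from `seed` and the frame
#' index, so lazily and eagerly rendered series are bit-identical.
#'
#' @param traj A `kinetic_trajectory` whose record times are the frame times.
#' @param geom A [make_geometry()] object.
#' @param optics Named list overriding `aggflux:::optics_defaults()`.
#' @param seed Integer seed for placement, motion and noise.
#' @param channels Named character vector mapping channel name -> label
#'   (e.g. `c(EGFP = "L1")`), with the optional morphology channel given as
#'   label `"morph"`. Default: morphology plus one channel per fluorescent
#'   label present in the trajectory.
#' @param lazy If `TRUE`, return a `lazy_series` whose frames are rendered
#'   on demand (constant memory); otherwise materialize the full array.
#'
#' @return List with `series` (an [image_series()] or `lazy_series`) and
#'   `truth` (list of `aggregates` and `cytosol` data frames; the aggregate
#'   table has per-frame id, x, y, z, compartment, per-label bound amounts,
#'   total fluorescence and a saturation flag).
#' @export
render_series <- function(traj, geom, optics = list(), seed = 1,
                          channels = NULL, lazy = FALSE) {
  opt <- merge_config(optics_defaults(), optics)
  if (is.null(channels)) {
    present <- FLUOR_LABELS[
      vapply(FLUOR_LABELS,
             function(l) any(traj$cyt[, l] > 0) ||
               (length(traj$A) && any(traj$A[l, , ] > 0)), TRUE)]
    if (!length(present)) present <- "L1"
    channels <- c(stats::setNames("morph", "morph"),
                  stats::setNames(present, paste0("ch_", present)))
  }
  bad <- setdiff(setdiff(channels, "morph"), AGG_LABELS)
  if (length(bad)) {
    stop("label channel requested but absent from trajectory: ",
         paste(bad, collapse = ", "))
  }
  maps <- build_weight_maps(geom, opt)
  pos <- place_aggregates(traj, geom, opt, seed)
  nt <- length(traj$times)
  nz <- geom$n_z
  Y <- geom$fov_shape[1]; X <- geom$fov_shape[2]
  nc <- length(channels)
  dt <- if (nt > 1) traj$times[2] - traj$times[1] else 1

  render_frame <- function(t) {
    set.seed(seed + 7919L * t)
    out <- array(0, dim = c(nc, nz, Y, X))
    for (ci in seq_len(nc)) {
      lab <- channels[ci]
      if (lab == "morph") {
        planes <- lapply(maps$morph, function(m) m * opt$gain_morph)
      } else {
        planes <- lapply(maps$cyt,
                         function(m) m * (traj$cyt[t, lab] * opt$gain_cyt))
        if (nrow(traj$agg)) {
          for (i in seq_len(nrow(traj$agg))) {
            if (is.na(pos[i, t, 1])) next
            amt <- traj$A[lab, i, t]
            if (amt <= 0) next
            planes <- add_punctum(planes, pos[i, t, 1], pos[i, t, 2],
                                  pos[i, t, 3], amt * opt$gain_agg,
                                  opt$sigma_xy, opt$sigma_z)
          }
        }
      }
      for (z in seq_len(nz)) {
        out[ci, z, , ] <- apply_noise(planes[[z]], opt)
      }
    }
    out
  }

  fluor_ch <- channels[channels != "morph"]
  truth_agg <- NULL
  if (nrow(traj$agg)) {
    rows <- list()
    for (t in seq_len(nt)) {
      alive <- which(!is.na(pos[, t, 1]))
      if (!length(alive)) next
      fl <- colSums(traj$A[FLUOR_LABELS, alive, t, drop = FALSE])
      df <- data.frame(
        frame = t, time_h = traj$times[t],
        aggregate_id = traj$agg$id[alive],
        x = pos[alive, t, 1], y = pos[alive, t, 2], z = pos[alive, t, 3],
        compartment = traj$agg$compartment[alive],
        fluor_total = as.numeric(fl),
        saturated = as.numeric(fl) * opt$gain_agg *
          (1 / (2 * pi * opt$sigma_xy^2)) *
          (1 / (sqrt(2 * pi) * opt$sigma_z)) + opt$bg_offset > MAX_DN,
        stringsAsFactors = FALSE)
      for (lab in AGG_LABELS) {
        df[[paste0("amount_", lab)]] <- traj$A[lab, alive, t]
      }
      rows[[length(rows) + 1L]] <- df
    }
    truth_agg <- do.call(rbind, rows)
  } else {
    truth_agg <- data.frame(frame = integer(), time_h = numeric(),
                            aggregate_id = integer(), x = numeric(),
                            y = numeric(), z = numeric(),
                            compartment = character(),
                            fluor_total = numeric(), saturated = logical())
  }
  truth_cyt <- data.frame(
    frame = rep(seq_len(nt), each = length(AGG_LABELS)),
    time_h = rep(traj$times, each = length(AGG_LABELS)),
    label = rep(AGG_LABELS, nt),
    amount = as.vector(t(traj$cyt)),
    stringsAsFactors = FALSE)
  truth <- list(aggregates = truth_agg, cytosol = truth_cyt)

  meta <- list(dt = dt, z_step = geom$z_step,
               channel_names = names(channels),
               pixel_size = geom$pixel_size, t0 = traj$times[1])
  if (lazy) {
    series <- structure(
      c(meta, list(n_t = nt, frame = render_frame, channels = channels)),
      class = "lazy_series")
  } else {
    data <- array(0, dim = c(nt, nc, nz, Y, X))
    for (t in seq_len(nt)) data[t, , , , ] <- render_frame(t)
    series <- image_series(data, dt = meta$dt, z_step = meta$z_step,
                           channel_names = meta$channel_names,
                           pixel_size = meta$pixel_size, t0 = meta$t0)
  }
  list(series = series, truth = truth)
}

#' @export
print.lazy_series <- function(x, ...) {
  cat(sprintf("<lazy_series> T=%d, channels: %s (frames rendered on demand)\n",
              x$n_t, paste(x$channel_names, collapse = ", ")))
  invisible(x)
}
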