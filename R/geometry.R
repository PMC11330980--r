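# Synthetic neuron geometry: soma/nucleus masks plus dendrite and axon
# skeleton polylines on a pixel grid. Coordinates are 0-based continuous
# (pixel centers at integers); z is a 0-based plane index.

geometry_defaults <- function() {
  list(
    fov_shape = c(480L, 640L),   # (Y, X) px
    pixel_size = 0.3,            # um/px (40x confocal regime)
    n_z = 12L,
    z_step = 0.8,                # um
    n_neurons = 2L,
    n_bg_axons = NULL,           # default: 2 per neuron (axons of unseen cells)
    soma_radius = c(10, 14),     # px, sampled uniformly
    nucleus_frac = 0.6,          # nucleus radius / soma radius
    n_dendrites = 4L,
    dendrite_length = c(60, 180),# px
    dendrite_width = 3,          # px
    axon_width = 1,              # px (axons thinner than dendrites)
    axon_max_len = 1500,         # px safety bound on axon walks
    step_px = 4,                 # waypoint spacing of the random walks
    dendrite_curv = 0.22,        # direction jitter (rad) per waypoint
    axon_curv = 0.08)
}

merge_config <- function(defaults, config) {
  if (is.null(config)) return(defaults)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(config)] <- config
  defaults
}

# random-walk polyline from `start` with heading `dir0`; returns waypoints
# (matrix x, y). Stops after max_len of travel or (if stop_at_exit) on
# leaving the FOV; the first out-of-bounds point is kept for truncation.
rw_polyline <- function(start, dir0, step, curv_sd, max_len, fov,
                        stop_at_exit = TRUE) {
  n_max <- ceiling(max_len / step) + 1L
  pts <- matrix(NA_real_, n_max, 2)
  pts[1, ] <- start
  th <- dir0
  for (i in 2:n_max) {
    th <- th + stats::rnorm(1, 0, curv_sd)
    pts[i, ] <- pts[i - 1, ] + step * c(cos(th), sin(th))
    out <- pts[i, 1] < 0 || pts[i, 1] > fov[2] - 1 ||
           pts[i, 2] < 0 || pts[i, 2] > fov[1] - 1
    if (out && stop_at_exit) return(pts[seq_len(i), , drop = FALSE])
  }
  pts[seq_len(n_max), , drop = FALSE]
}

# densify a waypoint polyline to ~0.5 px spacing, truncated at the FOV edge;
# returns list(pts, cum, exits)
densify_polyline <- function(way, fov, spacing = 0.5) {
  seg <- sqrt(rowSums(diff(way)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(NULL)
  s <- seq(0, total, by = spacing)
  x <- stats::approx(cum, way[, 1], xout = s)$y
  y <- stats::approx(cum, way[, 2], xout = s)$y
  inside <- x >= 0 & x <= fov[2] - 1 & y >= 0 & y <= fov[1] - 1
  exits <- any(!inside)
  if (all(!inside)) return(NULL)
  last <- if (exits) which(!inside)[1] - 1L else length(s)
  if (last < 2L) return(NULL)
  keep <- seq_len(last)
  list(pts = cbind(x = x[keep], y = y[keep]), cum = s[keep] - s[1],
       exits = exits)
}

#' Generate a synthetic neuron geometry
#'
#' Lays out `n_neurons` somata (with concentric nuclei) in the field of
#' view, grows dendrites and one axon per neuron as persistent random walks,
#' and adds background axons entering from the FOV boundary (axonal segments
#' of neurons outside the field, which in the morphology channel are
#' rendered only faintly). Reproducible per seed.
#'
#' @param seed Integer seed.
#' @param config Named list overriding the defaults (see
#'   `aggflux:::geometry_defaults()`): `fov_shape` (Y, X), `pixel_size`,
#'   `n_z`, `z_step`, `n_neurons`, `n_bg_axons`, soma/dendrite/axon shape
#'   parameters.
#'
#' @return An object of class `neuron_geometry`: `fov_shape`, `pixel_size`,
#'   `n_z`, `z_step`, `nucleus_mask` and `soma_mask` (Y x X logical),
#'   `somas` (data frame: neuron, cx, cy, r, r_nuc, z_soma), `skeletons`
#'   (list of polylines with fields `id`, `compartment` ("axon"/"dendrite"),
#'   `neuron`, `pts` (x, y), `cum` (arc length), `z_level`, `exits_fov`),
#'   `n_neurons`, `config`.
#' @export
make_geometry <- function(seed, config = list()) {
  cfg <- merge_config(geometry_defaults(), config)
  set.seed(seed)
  fov <- as.integer(cfg$fov_shape)
  Y <- fov[1]; X <- fov[2]
  n <- as.integer(cfg$n_neurons)
  r_max <- max(cfg$soma_radius)
  if (n > 0 && n * (6 * r_max)^2 > Y * X) {
    stop("FOV too small for requested neuron count")
  }
  if (is.null(cfg$n_bg_axons)) cfg$n_bg_axons <- 2L * n
  z_mid <- (cfg$n_z - 1) / 2

  somas <- data.frame(neuron = integer(), cx = numeric(), cy = numeric(),
                      r = numeric(), r_nuc = numeric(), z_soma = numeric())
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:300) {
      r <- stats::runif(1, cfg$soma_radius[1], cfg$soma_radius[2])
      cx <- stats::runif(1, r + 2, X - 1 - r - 2)
      cy <- stats::runif(1, r + 2, Y - 1 - r - 2)
      if (!nrow(somas) ||
          all((somas$cx - cx)^2 + (somas$cy - cy)^2 > (3 * r_max)^2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("FOV too small for requested neuron count")
    somas <- rbind(somas, data.frame(
      neuron = i, cx = cx, cy = cy, r = r, r_nuc = cfg$nucleus_frac * r,
      z_soma = round(z_mid + stats::runif(1, -1, 1))))
  }

  nucleus_mask <- matrix(FALSE, Y, X)
  soma_mask <- matrix(FALSE, Y, X)
  fill_disc <- function(mask, cx, cy, r) {
    px <- disk_pixels(c(Y, X), c(cx, cy), r)
    mask[px] <- TRUE
    mask
  }
  for (i in seq_len(nrow(somas))) {
    soma_mask <- fill_disc(soma_mask, somas$cx[i], somas$cy[i], somas$r[i])
    nucleus_mask <- fill_disc(nucleus_mask, somas$cx[i], somas$cy[i],
                              somas$r_nuc[i])
  }

  skeletons <- list()
  sk_id <- 0L
  add_skel <- function(way, compartment, neuron, z_level) {
    d <- densify_polyline(way, fov)
    if (is.null(d)) return(invisible(NULL))
    sk_id <<- sk_id + 1L
    skeletons[[sk_id]] <<- list(
      id = sk_id, compartment = compartment, neuron = neuron,
      pts = d$pts, cum = d$cum, z_level = as.integer(z_level),
      exits_fov = d$exits)
    invisible(NULL)
  }
  for (i in seq_len(n)) {
    s <- somas[i, ]
    th0 <- stats::runif(1, 0, 2 * pi)
    nd <- cfg$n_dendrites
    for (k in seq_len(nd)) {
      th <- th0 + 2 * pi * (k - 1) / nd + stats::rnorm(1, 0, 0.25)
      len <- stats::runif(1, cfg$dendrite_length[1], cfg$dendrite_length[2])
      start <- c(s$cx, s$cy) + s$r * c(cos(th), sin(th))
      way <- rw_polyline(start, th, cfg$step_px, cfg$dendrite_curv, len, fov)
      add_skel(way, "dendrite", i,
               max(0, min(cfg$n_z - 1, s$z_soma + sample(-1:1, 1))))
    }
    th_ax <- th0 + stats::runif(1, 0, 2 * pi)
    start <- c(s$cx, s$cy) + s$r * c(cos(th_ax), sin(th_ax))
    way <- rw_polyline(start, th_ax, cfg$step_px, cfg$axon_curv,
                       cfg$axon_max_len, fov)
    add_skel(way, "axon", i, sample.int(cfg$n_z, 1) - 1L)
  }
  for (b in seq_len(cfg$n_bg_axons)) {
    side <- sample.int(4, 1)  # 1 left, 2 right, 3 top, 4 bottom
    start <- switch(side,
                    c(0, stats::runif(1, 0, Y - 1)),
                    c(X - 1, stats::runif(1, 0, Y - 1)),
                    c(stats::runif(1, 0, X - 1), 0),
                    c(stats::runif(1, 0, X - 1), Y - 1))
    inward <- switch(side, 0, pi, pi / 2, -pi / 2)
    th <- inward + stats::runif(1, -0.6, 0.6)
    # nudge inside so the walk does not terminate on its first point
    start <- start + 0.6 * c(cos(th), sin(th))
    way <- rw_polyline(start, th, cfg$step_px, cfg$axon_curv,
                       cfg$axon_max_len, fov)
    add_skel(way, "axon", NA_integer_, sample.int(cfg$n_z, 1) - 1L)
  }

  structure(
    list(fov_shape = fov, pixel_size = cfg$pixel_size, n_z = cfg$n_z,
         z_step = cfg$z_step, nucleus_mask = nucleus_mask,
         soma_mask = soma_mask, somas = somas, skeletons = skeletons,
         n_neurons = n, config = cfg, seed = seed),
    class = "neuron_geometry")
}

#' @export
print.neuron_geometry <- function(x, ...) {
  comp <- vapply(x$skeletons, `[[`, character(1), "compartment")
  cat(sprintf("<neuron_geometry> %dx%d px, %d z-planes, %d neuron(s), %d dendrite(s), %d axon(s)\n",
              x$fov_shape[1], x$fov_shape[2], x$n_z, x$n_neurons,
              sum(comp == "dendrite"), sum(comp == "axon")))
  invisible(x)
}
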