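# Shared fixtures, built in code and cached per test session.
# Reduced problem sizes are used throughout: 240 x 320 px (quarter-area)
# or smaller fields, short series.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small localization scene: detection/tracking/classification substrate
loc_sim <- function() {
  fixture("loc_sim", function() {
    simulate_experiment(
      "localization_WT",
      config = list(fov_shape = c(240L, 320L), duration_h = 8),
      seed = 11)
  })
}

loc_detections <- function() {
  fixture("loc_det", function() detect_series(loc_sim()$series, "EGFP"))
}

loc_tracks <- function() {
  fixture("loc_tracks", function() link_tracks(loc_detections()))
}

morph_projection <- function(sim) {
  fr <- get_frame(sim$series, 1)
  mi <- match("morph", sim$series$channel_names)
  max_project(array(fr[mi, , , ], dim = dim(fr)[2:4]))
}

# synthetic Gaussian punctum image (no rendering machinery)
punctum_image <- function(dim_yx, x, y, amplitude, sigma = 1.3,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  img <- matrix(0, dim_yx[1], dim_yx[2])
  xs <- 0:(dim_yx[2] - 1); ys <- 0:(dim_yx[1] - 1)
  for (i in seq_along(x)) {
    img <- img + amplitude[i] *
      outer(exp(-(ys - y[i])^2 / (2 * sigma^2)),
            exp(-(xs - x[i])^2 / (2 * sigma^2)))
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        dim_yx[1], dim_yx[2])
  }
  img
}

# brute-force optimal frame-pair assignment by permutation enumeration
brute_force_assignment <- function(px, py, dx, dy, d_max) {
  n_p <- length(px); n_d <- length(dx)
  if (n_p == 0 || n_d == 0) return(rep(NA_integer_, n_d))
  dist <- sqrt(outer(px, dx, "-")^2 + outer(py, dy, "-")^2)
  best <- NULL; best_cost <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  k <- min(n_p, n_d)
  for (sel_d in utils::combn(n_d, k, simplify = FALSE)) {
    for (sel_p in perms(seq_len(n_p))) {
      sel_p <- sel_p[seq_len(k)]
      d <- dist[cbind(sel_p, sel_d)]
      if (any(d > d_max)) next
      cost <- sum(d)
      if (cost < best_cost) {
        best_cost <- cost
        best <- rep(NA_integer_, n_d)
        best[sel_d] <- sel_p
      }
    }
  }
  if (is.null(best)) rep(NA_integer_, n_d) else best
}
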