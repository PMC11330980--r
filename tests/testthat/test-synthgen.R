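# Geometry generation and rendering.

test_that("geometry is reproducible per seed and validates its config", {
  cfg <- list(fov_shape = c(120L, 160L), n_neurons = 1L)
  g1 <- make_geometry(21, cfg)
  g2 <- make_geometry(21, cfg)
  expect_identical(g1$somas, g2$somas)
  expect_identical(g1$skeletons, g2$skeletons)
  g3 <- make_geometry(22, cfg)
  expect_false(identical(g1$somas, g3$somas))

  expect_error(make_geometry(1, list(fov_shape = c(40L, 40L),
                                     n_neurons = 5L)),
               "FOV too small")
  expect_error(make_geometry(1, list(bogus_key = 1)), "unknown config")
})

test_that("zero neurons give empty masks and no skeletons", {
  g <- make_geometry(5, list(fov_shape = c(80L, 100L), n_neurons = 0L))
  expect_false(any(g$soma_mask))
  expect_false(any(g$nucleus_mask))
  expect_equal(length(g$skeletons), 0)
})

test_that("nucleus is contained in soma; at least one axon exits the FOV", {
  g <- make_geometry(7, list(fov_shape = c(240L, 320L), n_neurons = 2L))
  expect_true(all(g$soma_mask[g$nucleus_mask]))
  comp <- vapply(g$skeletons, `[[`, character(1), "compartment")
  exits <- vapply(g$skeletons, `[[`, logical(1), "exits_fov")
  expect_true(any(comp == "axon" & exits))
  # all skeleton points lie inside the FOV
  for (sk in g$skeletons) {
    expect_true(all(sk$pts[, 1] >= 0 & sk$pts[, 1] <= g$fov_shape[2] - 1))
    expect_true(all(sk$pts[, 2] >= 0 & sk$pts[, 2] <= g$fov_shape[1] - 1))
  }
})

test_that("a zero-amount trajectory with noise sources off renders all-zero", {
  p <- kinetic_params(0, 0, 0, 0, 0, 0)
  tr <- simulate_kinetics(p, horizon = 2, record_dt = 1)
  geom <- make_geometry(3, list(fov_shape = c(100L, 120L), n_z = 3L,
                                n_neurons = 1L))
  rend <- render_series(tr, geom,
                        optics = list(bg_offset = 0, read_sd = 0,
                                      gain_morph = 0),
                        seed = 1, channels = c(EGFP = "L1"))
  expect_true(all(rend$series$data == 0))
})

test_that("a noiseless punctum lands within 0.25 px of ground truth", {
  p <- kinetic_params(0, 0, 0, 0, 0, 0)
  A <- matrix(0, 5, 1, dimnames = list(aggflux:::AGG_LABELS, NULL))
  A["L1", 1] <- 2
  st <- cell_state(cyt = c(L1 = 0), A = A,
                   agg = data.frame(id = 1L, birth_time = 0,
                                    compartment = "axon"))
  tr <- simulate_kinetics(p, horizon = 2, record_dt = 2, state = st)
  geom <- make_geometry(4, list(fov_shape = c(120L, 160L), n_z = 6L,
                                n_neurons = 1L))
  rend <- render_series(tr, geom,
                        optics = list(poisson = FALSE, read_sd = 0,
                                      bg_offset = 0, gain_cyt = 0,
                                      gain_morph = 0, motion_step = 0,
                                      quantize = FALSE),
                        seed = 2, channels = c(EGFP = "L1"))
  g <- rend$truth$aggregates[1, ]
  proj <- max_project(array(rend$series$data[1, 1, , , ],
                            dim = dim(rend$series$data)[3:5]))
  # intensity-weighted centroid of the rendered punctum
  wsum <- sum(proj)
  xs <- 0:(ncol(proj) - 1); ys <- 0:(nrow(proj) - 1)
  cx <- sum(proj %*% xs) / wsum
  cy <- sum(t(proj) %*% ys) / wsum
  expect_lt(abs(cx - g$x), 0.25)
  expect_lt(abs(cy - g$y), 0.25)
})

test_that("rendering is photometrically linear pre-noise", {
  p <- kinetic_params(0, 0, 0, 0, 0, 0)
  geom <- make_geometry(4, list(fov_shape = c(80L, 100L), n_z = 4L,
                                n_neurons = 1L))
  total <- function(amount) {
    A <- matrix(0, 5, 1, dimnames = list(aggflux:::AGG_LABELS, NULL))
    A["L1", 1] <- amount
    st <- cell_state(cyt = c(L1 = 0), A = A,
                     agg = data.frame(id = 1L, birth_time = 0,
                                      compartment = "dendrite"))
    tr <- simulate_kinetics(p, horizon = 1, record_dt = 1, state = st)
    rend <- render_series(tr, geom,
                          optics = list(poisson = FALSE, read_sd = 0,
                                        bg_offset = 0, gain_cyt = 0,
                                        gain_morph = 0, motion_step = 0,
                                        quantize = FALSE, gain_agg = 100),
                          seed = 9, channels = c(EGFP = "L1"))
    sum(rend$series$data[1, 1, , , ])
  }
  expect_equal(total(4) / total(2), 2, tolerance = 1e-3)
})

test_that("noise model: background variance tracks the Poisson mean", {
  geom <- make_geometry(6, list(fov_shape = c(100L, 100L), n_z = 1L,
                                n_neurons = 0L, n_bg_axons = 0L))
  p <- kinetic_params(0, 0, 0, 0, 0, 0)
  tr <- simulate_kinetics(p, horizon = 1, record_dt = 1)
  rend <- render_series(tr, geom, optics = list(bg_offset = 50),
                        seed = 3, channels = c(EGFP = "L1"))
  px <- as.numeric(rend$series$data[1, 1, 1, , ])
  expect_lt(abs(stats::var(px) / mean(px) - 1), 0.2)
})

test_that("rendered data and ground truth agree on aggregate count per frame", {
  sim <- loc_sim()
  tr <- sim$truth$aggregates
  for (f in seq_len(n_frames(sim$series))) {
    expect_equal(sum(tr$frame == f), nrow(sim$truth$aggregates) /
                   n_frames(sim$series))
  }
  expect_setequal(unique(tr$aggregate_id), sim$trajectory$agg$id)
})

test_that("default acquisition geometry: 12 z-planes, 640x480, 12-bit", {
  p <- kinetic_params(0, 0, 0, 0, 0, 0)
  tr <- simulate_kinetics(p, horizon = 1, record_dt = 1,
                          state = cell_state(cyt = c(L1 = 100)))
  geom <- make_geometry(8)   # default config
  rend <- render_series(tr, geom, seed = 1,
                        channels = c(morph = "morph", EGFP = "L1"))
  expect_equal(dim(rend$series$data), c(2, 2, 12, 480, 640))
  expect_lte(max(rend$series$data), 4095)
  expect_gte(min(rend$series$data), 0)
  expect_equal(geom$z_step, 0.8)
})

test_that("same seed and config give bit-identical series; lazy equals eager", {
  cfg <- list(fov_shape = c(100L, 120L), n_z = 3L, duration_h = 4)
  s1 <- simulate_experiment("localization_WT", cfg, seed = 31)
  s2 <- simulate_experiment("localization_WT", cfg, seed = 31)
  expect_identical(s1$series$data, s2$series$data)
  expect_identical(s1$truth$aggregates, s2$truth$aggregates)

  s3 <- simulate_experiment("localization_WT", c(cfg, list(lazy = TRUE)),
                            seed = 31)
  for (f in seq_len(n_frames(s1$series))) {
    expect_identical(get_frame(s3$series, f), get_frame(s1$series, f))
  }
})

test_that("unknown protocols and absent label channels error clearly", {
  expect_error(simulate_experiment("bogus"), "valid protocols")
  p <- kinetic_params(0, 0, 0, 0, 0, 0)
  tr <- simulate_kinetics(p, horizon = 1, record_dt = 1)
  geom <- make_geometry(3, list(fov_shape = c(40L, 40L), n_z = 2L,
                                n_neurons = 0L))
  expect_error(render_series(tr, geom, channels = c(bad = "nope"),
                             seed = 1),
               "absent")
})

test_that("frap protocol timing: 5-min frames over 5 h plus baseline", {
  # 61 recovery samples after one pre-bleach frame at 5-min spacing
  cfg <- protocol_defaults("frap")
  expect_equal(cfg$frame_dt, 5 / 60)
  expect_equal(cfg$duration_h, 5)
  n_expected <- cfg$duration_h / cfg$frame_dt + 1
  expect_equal(n_expected, 61)
})

test_that("longterm_KR places nuclear aggregates; longterm_WT never does", {
  wt <- kinetic_preset("WT")
  expect_equal(unname(wt$placement["nucleus"]), 0)
  kr <- kinetic_preset("KR")
  expect_equal(unname(kr$placement["nucleus"]), 0.5)
  set.seed(2)
  comps_wt <- sample(aggflux:::AGG_COMPARTMENTS, 300, replace = TRUE,
                     prob = wt$placement)
  expect_false("nucleus" %in% comps_wt)
})
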