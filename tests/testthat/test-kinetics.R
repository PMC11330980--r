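# Exchange-kinetics model: integrator correctness, conservation, label
# bookkeeping, steady states, closed-form FRAP limit.

test_that("null dynamics leave any state unchanged", {
  p0 <- kinetic_params(0, 0, 0, 0, 0, 0)
  A <- matrix(0, 5, 1, dimnames = list(aggflux:::AGG_LABELS, NULL))
  A["dark", 1] <- 1
  st <- cell_state(cyt = c(dark = 5, L1 = 2), A = A,
                   agg = data.frame(id = 1L, birth_time = 0,
                                    compartment = "axon"))
  st2 <- step_state(st, p0, dt = 10)
  expect_equal(st2$cyt, st$cyt)
  expect_equal(st2$A, st$A)
})

test_that("single aggregate under constant cytosol follows the closed form", {
  # huge volume makes the per-aggregate drain on concentration negligible,
  # holding c at c0; then a(t) = (k_on c0 / k_off)(1 - exp(-k_off t))
  k_on <- 0.05; k_off <- 0.2; c0 <- 10
  p <- kinetic_params(0, 0, 0, 0, k_on, k_off, volume = 1e9)
  st <- cell_state(cyt = c(L1 = c0),
                   A = matrix(0, 5, 1,
                              dimnames = list(aggflux:::AGG_LABELS, NULL)),
                   agg = data.frame(id = 1L, birth_time = 0,
                                    compartment = "axon"))
  for (t_end in c(2, 10)) {
    st2 <- step_state(st, p, dt = t_end)
    a_expected <- k_on * c0 / k_off * (1 - exp(-k_off * t_end))
    expect_equal(unname(st2$A["L1", 1]), a_expected, tolerance = 1e-4)
  }
})

test_that("mass is conserved without synthesis or degradation", {
  # any preset structure, stochastic nucleation, label events: total mass
  # (cytosol * volume + bound) must persist to integrator tolerance
  for (seed in 1:3) {
    set.seed(seed)
    p <- kinetic_params(0, 0, 0.01, 1, 0.05, 0.1, volume = 0.5)
    st <- cell_state(cyt = c(dark = 50))
    m0 <- aggflux:::total_mass(st, p)
    sched <- label_schedule(c(10, 30, 60), c("label_L1", "block", "label_L2"))
    tr <- simulate_kinetics(p, horizon = 100, record_dt = 20,
                            schedule = sched, seed = seed, state = st)
    m1 <- aggflux:::total_mass(tr$final_state, p)
    expect_equal(m1, m0, tolerance = 1e-6)
  }
})

test_that("conservation matches at halved step size", {
  p <- kinetic_params(0, 0, 0, 0, 0.05, 0.1)
  st <- cell_state(cyt = c(dark = 50),
                   A = matrix(0, 5, 2,
                              dimnames = list(aggflux:::AGG_LABELS, NULL)),
                   agg = data.frame(id = 1:2, birth_time = 0,
                                    compartment = "axon"))
  s1 <- step_state(st, p, dt = 100, h_max = 0.05)
  s2 <- step_state(st, p, dt = 100, h_max = 0.025)
  expect_equal(sum(s1$cyt) + sum(s1$A), 50, tolerance = 1e-6)
  expect_equal(sum(s1$A), sum(s2$A), tolerance = 1e-6)
})

test_that("label events convert pools and bleaching preserves mass", {
  A <- matrix(0, 5, 2, dimnames = list(aggflux:::AGG_LABELS, NULL))
  A["L1", 1] <- 3; A["dark", 1] <- 1; A["L2", 2] <- 2
  st <- cell_state(cyt = c(dark = 10),
                   agg = data.frame(id = c(3L, 7L), birth_time = 0,
                                    compartment = c("axon", "soma")),
                   A = A)
  st1 <- apply_label_event(st, "label_L1")
  expect_equal(unname(st1$cyt["L1"]), 10)
  expect_equal(unname(st1$cyt["dark"]), 0)
  expect_equal(unname(st1$A["L1", 1]), 4)  # bound dark converted too
  expect_equal(st1$synth_label, "L1")

  st2 <- apply_label_event(st1, "block")
  expect_equal(st2$synth_label, "blocked")

  m_before <- sum(st2$cyt) + sum(st2$A)
  st3 <- apply_label_event(st2, "bleach", ids = 3L)
  expect_equal(unname(sum(st3$A[c("L1", "L2"), 1])), 0)  # fluorescence gone
  expect_equal(sum(st3$cyt) + sum(st3$A), m_before)  # mass in place
  expect_equal(unname(st3$A[, 2]), unname(st2$A[, 2]))
  expect_error(apply_label_event(st, "bleach", ids = 99L), "unknown")
})

test_that("label bookkeeping: pool totals equal the sum over labels", {
  p <- kinetic_preset("WT")
  p$volume <- 0.25
  sched <- pulse_chase_schedule(50)
  tr <- simulate_kinetics(p, horizon = 120, record_dt = 10,
                          schedule = sched, seed = 4)
  df <- as.data.frame(tr)
  cyt <- df[df$pool == "cytosol", ]
  by_t <- tapply(cyt$amount, cyt$time_h, sum)
  direct <- rowSums(tr$cyt)
  expect_equal(as.numeric(by_t[as.character(tr$times)]), unname(direct))
  expect_true(all(df$amount >= 0))
})

test_that("pulse-chase schedule: aggregate old label rises then falls, new rises", {
  # wild-type preset with a reference aggregate born at the labeling time
  p <- kinetic_preset("WT")
  pre <- simulate_kinetics(p, horizon = 240, record_dt = 240,
                           deterministic = TRUE)
  st <- pre$final_state
  st$agg <- rbind(st$agg, data.frame(id = st$next_id, birth_time = st$t,
                                     compartment = "axon"))
  st$A <- cbind(st$A, 0)
  ref <- st$next_id
  tr <- simulate_kinetics(p, horizon = 60, record_dt = 1.5,
                          schedule = pulse_chase_schedule(0), state = st,
                          deterministic = TRUE)
  j <- match(ref, tr$agg$id)
  l1 <- tr$A["L1", j, ]; l2 <- tr$A["L2", j, ]
  ipk <- which.max(l1)
  expect_gt(ipk, 3)                       # rises first
  expect_lt(ipk, length(l1))              # then falls
  expect_lt(l1[length(l1)], max(l1))
  expect_true(all(diff(l2) >= -1e-9))     # new label monotone increasing
})

test_that("KR preset: aggregate-bound second label stays exactly zero", {
  p <- kinetic_preset("KR")
  pre <- simulate_kinetics(p, horizon = 240, record_dt = 240,
                           deterministic = TRUE)
  st <- pre$final_state
  expect_gt(nrow(st$agg), 0)
  tr <- simulate_kinetics(p, horizon = 60, record_dt = 3,
                          schedule = pulse_chase_schedule(0), state = st,
                          deterministic = TRUE)
  expect_identical(max(tr$A["L2", , ]), 0)
  expect_gt(max(tr$cyt[, "L2"]), 0)  # cytosolic new label does accumulate
})

test_that("WT aggregate appearance is near-linear in time", {
  # slope stability across thirds of the window after nucleation onset
  p <- kinetic_preset("WT")
  tr <- simulate_kinetics(p, horizon = 480, record_dt = 4,
                          deterministic = TRUE)
  onset <- min(tr$agg$birth_time)
  tt <- seq(onset + 30, 480, length.out = 4)
  counts <- vapply(tt, function(t) sum(tr$agg$birth_time <= t), 0)
  slopes <- diff(counts) / diff(tt)
  expect_gt(min(slopes), 0)
  expect_lt(max(slopes) / min(slopes), 2.5)
})

test_that("equilibrium_cytosol matches trivial limits and long-run simulation", {
  expect_equal(as.numeric(equilibrium_cytosol(
    kinetic_params(0, 0.1, 0, 0, 0.01, 0.1), 5)), 0)
  expect_equal(as.numeric(equilibrium_cytosol(
    kinetic_params(1, 0.1, 0, 0, 0, 0.1), 0)), 10)
  expect_error(equilibrium_cytosol(kinetic_params(1, 0, 0, 0, 0, 0), 0),
               "steady state")

  # long-run simulation with nucleation frozen converges to the fixed point
  # (the slow relaxation mode of the exchanging preset has a ~600 h time
  # constant, hence the long horizon with a coarser — still accurate —
  # fixed step)
  for (preset in c("WT", "KR")) {
    p <- kinetic_preset(preset)
    p$k_nuc <- 0  # freeze nucleation
    n_agg <- 20
    cstar <- equilibrium_cytosol(p, n_agg)
    st <- cell_state(cyt = c(dark = 0.9 * as.numeric(cstar)),
                     A = matrix(0, 5, n_agg,
                                dimnames = list(aggflux:::AGG_LABELS, NULL)),
                     agg = data.frame(id = seq_len(n_agg), birth_time = 0,
                                      compartment = "axon"))
    tr <- simulate_kinetics(p, horizon = 6000, record_dt = 6000,
                            state = st, deterministic = TRUE, h_max = 0.25)
    expect_equal(sum(tr$final_state$cyt), as.numeric(cstar),
                 tolerance = 1e-3)
    if (p$k_off > 0) {
      expect_equal(mean(colSums(tr$final_state$A)),
                   as.numeric(attr(cstar, "a_star")), tolerance = 1e-3)
    }
  }
})

test_that("closed-form FRAP curve: permanent deposits and 9 h time constant", {
  kr <- kinetic_preset("KR")
  expect_true(all(frap_recovery_curve(kr, 100)$values == 0))

  wt <- kinetic_preset("WT")  # k_off = 1/9
  fc <- frap_recovery_curve(wt, c_ambient = 100, horizon = 5, dt = 5 / 60)
  expect_equal(fc$values[length(fc$values)], 1 - exp(-5 / 9),
               tolerance = 1e-9)
})

test_that("closed-form FRAP curve agrees with the full state simulation", {
  # constant-cytosol regime enforced by a huge simulated volume and no
  # synthesis/degradation (the ambient fluorescent pool must stay fixed)
  wt <- kinetic_preset("WT")
  wt$volume <- 1e9
  wt$k_nuc <- 0
  wt$s <- 0
  wt$k_deg <- 0
  c0 <- 100
  a_pre <- wt$k_on * c0 / wt$k_off
  A <- matrix(0, 5, 1, dimnames = list(aggflux:::AGG_LABELS, NULL))
  A["bleached", 1] <- a_pre  # fully bleached aggregate at equilibrium content
  st <- cell_state(cyt = c(L1 = c0), A = A,
                   agg = data.frame(id = 1L, birth_time = 0,
                                    compartment = "axon"))
  tr <- simulate_kinetics(wt, horizon = 5, record_dt = 5 / 60, state = st,
                          deterministic = TRUE)
  f_sim <- tr$A["L1", 1, ] / a_pre
  f_closed <- frap_recovery_curve(wt, c_ambient = c0, horizon = 5,
                                  dt = 5 / 60)$values
  expect_lt(max(abs(f_sim - f_closed)), 1e-3)
})

test_that("nucleation honors threshold and placement probabilities", {
  p <- kinetic_params(1, 0, 0.05, 30, 0, 0,
                      placement = c(axon = 0.5, dendrite = 0, soma = 0,
                                    nucleus = 0.5))
  tr <- simulate_kinetics(p, horizon = 120, record_dt = 20, seed = 9)
  expect_gt(nrow(tr$agg), 10)
  # no births before the threshold crossing (c = t here, so t = 30)
  expect_gt(min(tr$agg$birth_time), 30)
  expect_true(all(tr$agg$compartment %in% c("axon", "nucleus")))
})

test_that("step_state validates inputs and rejects invalid placements", {
  p <- kinetic_preset("WT")
  st <- cell_state(cyt = c(dark = 1))
  expect_error(step_state(st, p, dt = 0), "dt")
  expect_error(kinetic_params(1, 0.1, 0, 0, 0, 0,
                              placement = c(axon = 0.7, dendrite = 0,
                                            soma = 0, nucleus = 0.2)),
               "sum to 1")
  expect_error(kinetic_params(-1, 0.1, 0, 0, 0, 0), ">= 0")
})

test_that("presets round-trip through YAML", {
  for (nm in c("WT", "KR")) {
    p <- kinetic_preset(nm)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_params_yaml(p, path)
    q <- read_params_yaml(path)
    expect_equal(q$placement, p$placement)
    expect_equal(q$k_off, p$k_off)
    expect_equal(q$bind_labels, p$bind_labels)
    expect_equal(q$preset_name, p$preset_name)
  }
})
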