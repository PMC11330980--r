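# FRAP fitting and pulse-chase summaries.

test_that("noiseless single-exponential recovery is recovered exactly", {
  t <- seq(0, 5, by = 5 / 60)
  tr <- new_trace(t, 1 - exp(-t / 9))
  fit <- fit_frap(tr, bleach_time = 0,
                  fit_config = list(pre_bleach_value = 1))
  expect_true(fit$converged)
  expect_equal(fit$tau, 9, tolerance = 1e-3)
  expect_equal(fit$mobile_fraction, 1, tolerance = 1e-3)
})

test_that("a flat post-bleach trace is unidentifiable, not an error", {
  t <- seq(0, 5, by = 0.25)
  fit <- fit_frap(new_trace(t, rep(0.12, length(t))), bleach_time = 0)
  expect_false(fit$converged)
  expect_equal(fit$mobile_fraction, 0)
})

test_that("median tau over noisy traces is accurate and agrees with a grid oracle", {
  set.seed(99)
  t <- seq(0, 5, by = 5 / 60)
  true_tau <- 9
  grid_tau <- function(v) {
    taus <- exp(seq(log(0.5), log(60), length.out = 400))
    sse <- vapply(taus, function(tau) {
      e <- exp(-t / tau)
      sum(stats::lm.fit(cbind(1, e), v)$residuals^2)
    }, 0)
    taus[which.min(sse)]
  }
  fitted <- oracle <- numeric(100)
  for (i in 1:100) {
    v <- (1 - exp(-t / true_tau)) * (1 + stats::rnorm(length(t), 0, 0.05))
    fit <- fit_frap(new_trace(t, v), bleach_time = 0,
                    fit_config = list(pre_bleach_value = 1))
    fitted[i] <- fit$tau
    oracle[i] <- grid_tau(v)
  }
  expect_lt(abs(stats::median(fitted) / true_tau - 1), 0.10)
  expect_lt(abs(stats::median(fitted) / stats::median(oracle) - 1), 0.05)
})

test_that("fit_frap is scale-invariant", {
  set.seed(4)
  t <- seq(0, 5, by = 0.1)
  v <- 0.2 + 0.5 * (1 - exp(-t / 6)) + stats::rnorm(length(t), 0, 0.01)
  f1 <- fit_frap(new_trace(t, v), fit_config = list(pre_bleach_value = 1))
  f2 <- fit_frap(new_trace(t, 37 * v),
                 fit_config = list(pre_bleach_value = 37))
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f2$mobile_fraction, f1$mobile_fraction, tolerance = 1e-6)
})

test_that("fitted tau equals 1/k_off on model-generated recovery curves", {
  wt <- kinetic_preset("WT")
  tr <- frap_recovery_curve(wt, c_ambient = 100, horizon = 24, dt = 0.25)
  fit <- fit_frap(tr, bleach_time = 0,
                  fit_config = list(pre_bleach_value = 1))
  expect_true(fit$converged)
  expect_equal(fit$tau, 1 / wt$k_off, tolerance = 0.02)
})

test_that("pulse-chase metrics: trivial shapes and input validation", {
  t <- seq(0, 30, by = 1.5)
  old <- new_trace(t, exp(-t / 10))          # monotone decreasing
  new <- new_trace(t, rep(0.01, length(t)))  # flat at background
  pc <- pulse_chase_metrics(old, new,
                            pc_config = list(t_new_start = 5))
  expect_equal(pc$t_peak_old, 0)
  expect_false(pc$new_rise_present)
  expect_gt(pc$old_decay_rate, 0)

  rising <- new_trace(t, 0.01 + t / 30)
  pc2 <- pulse_chase_metrics(old, rising,
                             pc_config = list(t_new_start = 5))
  expect_true(pc2$new_rise_present)

  expect_error(pulse_chase_metrics(new_trace(0:1, 1:2), new_trace(0:1, 1:2)),
               "at least 3")
  expect_error(pulse_chase_metrics(old, new_trace(t + 0.5, t)),
               "time base")
})

test_that("WT and KR model traces are perfectly discriminated by new_rise_present", {
  run_pc <- function(preset) {
    p <- kinetic_preset(preset)
    pre <- simulate_kinetics(p, horizon = 240, record_dt = 240,
                             deterministic = TRUE)
    st <- pre$final_state
    st$agg <- rbind(st$agg, data.frame(id = st$next_id, birth_time = st$t,
                                       compartment = "axon"))
    st$A <- cbind(st$A, 0)
    tr <- simulate_kinetics(p, horizon = 60, record_dt = 1.5,
                            schedule = pulse_chase_schedule(0), state = st,
                            deterministic = TRUE)
    scale <- max(tr$A["L1", , ])  # measurement noise floor, both presets
    lapply(seq_len(nrow(tr$agg)), function(j) {
      set.seed(j)
      noise <- function() stats::rnorm(length(tr$times), 0, 0.005 * scale)
      old <- new_trace(tr$times, tr$A["L1", j, ] + noise(),
                       subject = tr$agg$id[j], channel = "old")
      new <- new_trace(tr$times, tr$A["L2", j, ] + noise(),
                       subject = tr$agg$id[j], channel = "new")
      pulse_chase_metrics(old, new,
                          pc_config = list(t_new_start = tr$times[1] + 5))
    })
  }
  wt <- run_pc("WT")
  kr <- run_pc("KR")
  expect_true(all(vapply(wt, `[[`, TRUE, "new_rise_present")))
  expect_false(any(vapply(kr, `[[`, TRUE, "new_rise_present")))
})

test_that("deterministic WT pulse-chase: reference aggregate peaks near 30 h", {
  sim <- simulate_experiment(
    "pulsechase_WT",
    config = list(deterministic = TRUE, fov_shape = c(120L, 160L),
                  n_z = 2L, volume = 1),
    seed = 1)
  j <- match(sim$reference_id, sim$trajectory$agg$id)
  old <- new_trace(sim$trajectory$times, sim$trajectory$A["L1", j, ])
  new <- new_trace(sim$trajectory$times, sim$trajectory$A["L2", j, ])
  pc <- pulse_chase_metrics(old, new,
                            pc_config = list(t_new_start = sim$t_start + 5))
  expect_gt(pc$t_peak_old, 24)
  expect_lt(pc$t_peak_old, 36)
  expect_true(pc$new_rise_present)
})
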