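# FRAP recovery fitting and pulse-chase two-channel turnover summaries.

frap_defaults <- function() {
  list(min_points = 5,      # required post-bleach samples
       amp_snr = 2,         # fitted amplitude must exceed amp_snr * rms
       pre_bleach_value = NULL)  # default: mean of pre-bleach samples, or 1
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of `F(t) = F_inf - (F_inf - F0) * exp(-(t - t_bleach) / tau)`
#' to the post-bleach points of a trace. The mobile fraction is
#' `(F_inf - F0) / (F_pre - F0)` with `F_pre` the mean pre-bleach value
#' (1 for a trace normalized to its pre-bleach baseline). A flat trace has
#' no identifiable time constant and is reported with `converged = FALSE`
#' rather than as an error.
#'
#' @param trace An [new_trace()] (times in h).
#' @param bleach_time Time of the bleach event (h); points at or after it
#'   are fitted.
#' @param fit_config Named list overriding `aggflux:::frap_defaults()`.
#' @return An object of class `frap_fit`: `tau` (h), `mobile_fraction`,
#'   `f0`, `f_inf`, `residual_rms`, `converged`, `n_points`, `message`.
#' @export
fit_frap <- function(trace, bleach_time = 0, fit_config = list()) {
  cfg <- merge_config(frap_defaults(), fit_config)
  stopifnot(inherits(trace, "agg_trace"))
  post <- trace$times >= bleach_time - 1e-9
  t <- trace$times[post] - bleach_time
  v <- trace$values[post]
  if (length(t) < cfg$min_points) {
    stop("need at least ", cfg$min_points, " post-bleach points")
  }
  f_pre <- cfg$pre_bleach_value
  if (is.null(f_pre)) {
    pre <- trace$values[!post]
    f_pre <- if (length(pre)) mean(pre) else 1
  }
  out <- list(tau = NA_real_, mobile_fraction = NA_real_, f0 = v[1],
              f_inf = NA_real_, residual_rms = NA_real_, converged = FALSE,
              n_points = length(t), message = "",
              data = data.frame(t = t, v = v))
  class(out) <- "frap_fit"
  # for fixed tau the model F_inf + (F0 - F_inf) exp(-t/tau) is linear in
  # (F_inf, F0): profile the residual sum of squares over tau (log grid +
  # golden-section refinement), then polish with Levenberg-Marquardt
  span <- max(t)
  sse_for <- function(tau) {
    e <- exp(-t / tau)
    sum(stats::lm.fit(cbind(1, e), v)$residuals^2)
  }
  tau_max <- span * 20
  taus <- exp(seq(log(span / 100), log(tau_max), length.out = 60))
  sse <- vapply(taus, sse_for, 0)
  i <- which.min(sse)
  opt <- stats::optimize(sse_for,
                         c(taus[max(1, i - 1)],
                           taus[min(length(taus), i + 1)]))
  tau_hat <- opt$minimum
  e <- exp(-t / tau_hat)
  cf_lin <- stats::lm.fit(cbind(1, e), v)$coefficients
  f_inf_hat <- unname(cf_lin[1]); f0_hat <- unname(cf_lin[1] + cf_lin[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ f_inf - (f_inf - f0) * exp(-t / tau),
      start = list(f_inf = f_inf_hat, f0 = f0_hat, tau = tau_hat),
      lower = c(-Inf, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && stats::coef(fit)["tau"] > 0) {
    cf <- stats::coef(fit)
    out$f_inf <- unname(cf["f_inf"]); out$f0 <- unname(cf["f0"])
    out$tau <- unname(cf["tau"])
    rms <- sqrt(mean(stats::residuals(fit)^2))
  } else {
    out$f_inf <- f_inf_hat; out$f0 <- f0_hat; out$tau <- tau_hat
    rms <- sqrt(opt$objective / length(t))
  }
  out$residual_rms <- rms
  amp <- out$f_inf - out$f0
  denom <- f_pre - out$f0
  out$mobile_fraction <- if (abs(denom) > 1e-12) amp / denom else NA_real_
  noise_floor <- max(rms, 1e-9 * max(abs(v), 1))
  if (amp <= cfg$amp_snr * noise_floor) {
    # flat or noise-dominated recovery: tau unidentifiable
    out$converged <- FALSE
    out$mobile_fraction <- max(0, min(out$mobile_fraction, 1, na.rm = TRUE))
    if (amp <= 0 || rms == 0) out$mobile_fraction <- 0
    out$message <- "recovery amplitude indistinguishable from noise"
    return(out)
  }
  if (out$tau >= 0.95 * tau_max) {
    out$converged <- FALSE
    out$message <- "time constant not resolved within the observation window"
    return(out)
  }
  out$converged <- out$tau > 0
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<frap_fit> tau=%.3g h, mobile fraction=%.3f, f0=%.3g, f_inf=%.3g (rms %.3g)\n",
                x$tau, x$mobile_fraction, x$f0, x$f_inf, x$residual_rms))
  } else {
    cat("<frap_fit> not converged:", x$message, "\n")
  }
  invisible(x)
}

pc_defaults <- function() {
  list(smooth_window = 3,   # frames, moving average for peak finding
       k_background = 3,    # MAD units above pre-addition background
       rel_floor = 0.1,     # a rise must also reach this fraction of the
                            # old-label peak (same intensity scale) to be
                            # a meaningful exchange signal
       t_new_start = NULL)  # time the second ligand was added (h);
                            # default: first time of the new trace
}

moving_average <- function(v, w) {
  if (w <= 1 || length(v) < w) return(v)
  sm <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  # shrink the window at the edges instead of dropping them
  n <- length(v)
  h <- (w - 1) %/% 2
  for (i in which(is.na(sm))) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    sm[i] <- mean(v[lo:hi])
  }
  sm
}

#' Pulse-chase turnover summary for one aggregate
#'
#' Finds the time at which the old-label (first-ligand) trace peaks after
#' moving-average smoothing, fits a log-linear decay rate to the post-peak
#' segment, and tests whether the new-label (second-ligand) trace rises
#' above its pre-addition background (median + `k_background` MAD) and
#' above a fraction (`rel_floor`) of the old-label peak, so that residual
#' diffuse background on the same structure does not masquerade as
#' exchange.
#'
#' @param old_trace,new_trace [new_trace()] objects on a shared time base.
#' @param pc_config Named list overriding `aggflux:::pc_defaults()`.
#' @return An object of class `pulse_chase_summary`: `track_id`,
#'   `t_peak_old` (h, relative to the trace start), `old_decay_rate`
#'   (h^-1; NA if no post-peak decay is measurable), `new_rise_present`,
#'   `new_plateau_norm` (final smoothed new-label value divided by the
#'   background threshold; rise present iff > 1).
#' @export
pulse_chase_metrics <- function(old_trace, new_trace, pc_config = list()) {
  cfg <- merge_config(pc_defaults(), pc_config)
  stopifnot(inherits(old_trace, "agg_trace"), inherits(new_trace, "agg_trace"))
  if (length(old_trace$times) < 3 || length(new_trace$times) < 3) {
    stop("traces must have at least 3 points")
  }
  if (length(old_trace$times) != length(new_trace$times) ||
      any(abs(old_trace$times - new_trace$times) > 1e-6)) {
    stop("old and new traces must share a time base")
  }
  t0 <- old_trace$times[1]
  tt <- old_trace$times - t0
  sm_old <- moving_average(old_trace$values, cfg$smooth_window)
  sm_new <- moving_average(new_trace$values, cfg$smooth_window)
  ipk <- which.max(sm_old)
  t_peak <- tt[ipk]
  # post-peak log-linear decay
  decay <- NA_real_
  post <- seq(ipk, length(tt))
  ok <- post[sm_old[post] > 0]
  if (length(ok) >= 3) {
    fit <- stats::lm(log(sm_old[ok]) ~ tt[ok])
    decay <- -unname(stats::coef(fit)[2])
  }
  t_new <- if (is.null(cfg$t_new_start)) t0 else cfg$t_new_start
  pre <- new_trace$times < t_new - 1e-9
  if (any(pre)) {
    bg <- new_trace$values[pre]
  } else {
    bg <- new_trace$values[1]  # no pre-addition frames: first frame proxy
  }
  thr <- stats::median(bg) + cfg$k_background * stats::mad(bg, constant = 1.4826)
  # and the rise must be meaningful on the aggregate's own intensity scale
  thr <- max(thr, cfg$rel_floor * max(sm_old), 1e-12)
  plateau <- sm_new[length(sm_new)]
  norm <- plateau / thr
  structure(
    list(track_id = old_trace$subject, t_peak_old = t_peak,
         old_decay_rate = decay, new_rise_present = norm > 1,
         new_plateau_norm = norm),
    class = "pulse_chase_summary")
}

#' @export
print.pulse_chase_summary <- function(x, ...) {
  cat(sprintf("<pulse_chase_summary> track %s: old-label peak at %.2f h, decay %.3g /h, new label %s (plateau/threshold %.2f)\n",
              as.character(x$track_id), x$t_peak_old, x$old_decay_rate,
              if (x$new_rise_present) "rises" else "absent",
              x$new_plateau_norm))
  invisible(x)
}
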