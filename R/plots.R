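# Base-graphics diagnostics.

#' @export
plot.agg_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l",
                 xlab = "time (h)",
                 ylab = if (x$normalized) "fluorescence (t0 = 1)"
                        else "fluorescence (a.u.)",
                 main = sprintf("%s / %s", as.character(x$subject),
                                as.character(x$channel)), ...)
  invisible(x)
}

#' FRAP fit overlay
#'
#' Plots the post-bleach data points with the fitted single-exponential
#' recovery.
#'
#' @param x A `frap_fit` from [fit_frap()].
#' @param ... Passed to `plot`.
#' @export
plot.frap_fit <- function(x, ...) {
  if (is.null(x$data)) stop("fit carries no data (fitted before plotting?)")
  graphics::plot(x$data$t, x$data$v, pch = 16, cex = 0.6,
                 xlab = "time since bleach (h)", ylab = "fluorescence",
                 main = if (x$converged) {
                   sprintf("tau = %.2f h, mobile fraction = %.2f",
                           x$tau, x$mobile_fraction)
                 } else "not converged", ...)
  if (is.finite(x$tau)) {
    tt <- seq(0, max(x$data$t), length.out = 200)
    graphics::lines(tt, x$f_inf - (x$f_inf - x$f0) * exp(-tt / x$tau),
                    col = "red3", lwd = 2)
  }
  invisible(x)
}
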