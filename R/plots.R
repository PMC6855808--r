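#' Plot a binding-to-stability coupling curve
#'
#' @param x A `coupling_curve` from [couple_binding_to_stability()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coupling_curve <- function(x, ...) {
  graphics::plot(x$n_bound, x$fractional_effect, type = "b", pch = 16,
                 xlab = "bound lipids per pentamer",
                 ylab = "fractional stabilizing effect",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Plot a leaflet-resolved polar density map
#'
#' Displays the mean per-bin area density as an image in (radius, angle)
#' coordinates.
#'
#' @param x A `polar_density_map` from [polar_density()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.polar_density_map <- function(x, ...) {
  graphics::image(x = x$r_edges, y = x$theta_edges, z = x$values,
                  xlab = "r (Angstrom)", ylab = "theta (rad)",
                  main = sprintf("%s density, %s leaflet", x$species,
                                 x$leaflet), ...)
  invisible(x)
}

#' Plot a rate-versus-delay course with its fitted decomposition
#'
#' @param x A `rate_course` data frame from [aggregate_rates()].
#' @param fit Optional `rate_course_fit` overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rate_course <- function(x, fit = NULL, ...) {
  graphics::plot(x$delay_s, x$k_mean, log = "x", pch = 16,
                 xlab = "agonist delay (s)", ylab = "initial rate (1/s)", ...)
  graphics::arrows(x$delay_s, x$k_mean - x$k_sd, x$delay_s,
                   x$k_mean + x$k_sd, angle = 90, code = 3, length = 0.02)
  if (!is.null(fit)) {
    tt <- exp(seq(log(min(x$delay_s)), log(max(x$delay_s)),
                  length.out = 200))
    kk <- fit$offset + fit$A1 * exp(-tt / fit$tau1) +
      (if (fit$model == "double") fit$A2 * exp(-tt / fit$tau2) else 0)
    graphics::lines(tt, kk, col = 2)
  }
  invisible(x)
}
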