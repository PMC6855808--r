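#' Fit a fluorescence quench trace with a stretched exponential
#'
#' Sequential-mixing stopped-flow quench traces (Tl+ influx quenching an
#' encapsulated fluorophore) are heterogeneous across the liposome population
#' and are described by
#' F(t) = F_inf + (F_0 - F_inf) * exp(-(t/tau)^beta) with 0 < beta <= 1.
#' Traces whose total amplitude does not rise above the noise floor are
#' flagged `no_flux` rather than treated as errors; their rate is zero.
#'
#' @param time Strictly increasing times in seconds (> 0, >= 20 samples).
#' @param fluorescence Fluorescence values (arbitrary units).
#' @return An object of class `stretched_fit`: list with `f0`, `f_inf`,
#'   `tau` (s), `beta`, `rmse` and logical `no_flux`.
#' @export
#' @examples
#' tt <- exp(seq(log(5e-4), log(1), length.out = 100))
#' ff <- 0.2 + 0.8 * exp(-(tt / 0.05)^0.7)
#' fit_stretched(tt, ff)
fit_stretched <- function(time, fluorescence) {
  time <- as.numeric(time); ff <- as.numeric(fluorescence)
  if (length(time) != length(ff) || length(time) < 20L)
    stop("need >= 20 (time, fluorescence) samples")
  if (any(time <= 0) || any(diff(time) <= 0))
    stop("'time' must be strictly increasing and > 0")
  if (any(!is.finite(ff))) stop("fluorescence must be finite")

  # noise floor from first differences (robust to the decay trend)
  noise <- stats::mad(diff(ff)) / sqrt(2)
  amp <- diff(range(ff))
  if (amp < max(6 * noise, 1e-12)) {
    return(structure(list(f0 = mean(ff), f_inf = mean(ff), tau = Inf,
                          beta = 1, rmse = stats::sd(ff), no_flux = TRUE),
                     class = "stretched_fit"))
  }
  n <- length(ff)
  f0_0 <- mean(ff[1:max(3L, n %/% 20L)])
  fi_0 <- mean(ff[(n - max(3L, n %/% 20L) + 1L):n])
  half <- f0_0 - (f0_0 - fi_0) / 2
  tau_0 <- time[which.min(abs(ff - half))]
  if (!is.finite(tau_0) || tau_0 <= 0) tau_0 <- stats::median(time)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ff ~ fi + (f0 - fi) * exp(-(time / tau)^beta),
      start = list(f0 = f0_0, fi = fi_0, tau = tau_0, beta = 0.8),
      lower = c(f0 = -Inf, fi = -Inf, tau = 1e-8, beta = 1e-3),
      upper = c(f0 = Inf, fi = Inf, tau = 1e8, beta = 1),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(f0 = f0_0, f_inf = fi_0, tau = Inf, beta = 1,
                          rmse = stats::sd(ff), no_flux = TRUE),
                     class = "stretched_fit"))
  }
  cf <- stats::coef(fit)
  # post-fit screens: a fitted amplitude at the noise floor, or a decay that
  # completed before the first sample, carries no flux information
  if (abs(cf[["f0"]] - cf[["fi"]]) < 6 * noise || cf[["tau"]] < time[1]) {
    return(structure(list(f0 = cf[["f0"]], f_inf = cf[["fi"]], tau = Inf,
                          beta = 1, rmse = sqrt(mean(stats::resid(fit)^2)),
                          no_flux = TRUE),
                     class = "stretched_fit"))
  }
  structure(list(f0 = cf[["f0"]], f_inf = cf[["fi"]], tau = cf[["tau"]],
                 beta = cf[["beta"]], rmse = sqrt(mean(stats::resid(fit)^2)),
                 no_flux = FALSE),
            class = "stretched_fit")
}

#' @export
print.stretched_fit <- function(x, ...) {
  if (x$no_flux) cat("<stretched_fit> no flux (flat trace)\n")
  else cat(sprintf("<stretched_fit> tau = %.4g s, beta = %.3f, F0 = %.3g -> Finf = %.3g, rmse = %.3g\n",
                   x$tau, x$beta, x$f0, x$f_inf, x$rmse))
  invisible(x)
}

#' @export
coef.stretched_fit <- function(object, ...) {
  c(f0 = object$f0, f_inf = object$f_inf, tau = object$tau, beta = object$beta)
}

#' Initial Tl+ influx rate from a stretched-exponential fit
#'
#' Instantaneous relaxation rate of the stretched exponential evaluated at an
#' early fixed time (default 2 ms, before significant desensitization during
#' the quench phase): k = (beta/tau) * (t_eval/tau)^(beta - 1). For a no-flux
#' trace the rate is 0.
#'
#' @param fit A `stretched_fit`.
#' @param t_eval Evaluation time in seconds (default 0.002).
#' @return Rate in s^-1.
#' @export
initial_rate <- function(fit, t_eval = 0.002) {
  stopifnot(inherits(fit, "stretched_fit"))
  if (fit$no_flux) return(0)
  (fit$beta / fit$tau) * (t_eval / fit$tau)^(fit$beta - 1)
}

#' Screen repeats of one delay for outliers
#'
#' Deterministic surrogate for by-eye inspection of stopped-flow repeats: a
#' repeat is rejected when its fitted initial rate deviates from the
#' per-delay median by more than `mad_mult` scaled median absolute deviations,
#' or when its fit rmse exceeds `rmse_mult` times the median rmse. With fewer
#' than 3 repeats all are kept (with a warning when they disagree).
#'
#' @param fits List of `stretched_fit` objects for one delay.
#' @param t_eval Rate evaluation time in seconds (default 0.002).
#' @param mad_mult Rate MAD multiplier (default 3).
#' @param rmse_mult RMSE multiplier (default 3).
#' @return List with `kept` and `rejected` index vectors and `rates` (all
#'   fitted rates).
#' @export
screen_repeats <- function(fits, t_eval = 0.002, mad_mult = 3, rmse_mult = 3) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "stretched_fit")))
  rates <- vapply(fits, initial_rate, numeric(1), t_eval = t_eval)
  rmses <- vapply(fits, function(f) f$rmse, numeric(1))
  n <- length(fits)
  if (n < 3L) {
    if (n == 2L && diff(range(rates)) > 0.5 * max(abs(rates), 1e-12))
      warning("only 2 repeats and they disagree; both kept (screening needs >= 3)")
    return(list(kept = seq_len(n), rejected = integer(0), rates = rates))
  }
  md <- stats::median(rates)
  # scaled MAD (constant 1.4826), floored at 0.1% of the median so a gross
  # outlier among otherwise identical repeats is still caught
  s <- max(stats::mad(rates), 1e-3 * abs(md))
  bad_rate <- if (s > 0) abs(rates - md) > mad_mult * s else rep(FALSE, n)
  med_rmse <- stats::median(rmses)
  bad_rmse <- if (med_rmse > 0) rmses > rmse_mult * med_rmse else rep(FALSE, n)
  rejected <- which(bad_rate | bad_rmse)
  kept <- setdiff(seq_len(n), rejected)
  if (length(kept) == 0L)
    stop("aggregation error: all repeats rejected by the outlier screen")
  list(kept = kept, rejected = rejected, rates = rates)
}

#' Per-delay mean rates from screened repeats
#'
#' Fits every repeat with [fit_stretched()], screens repeats within each
#' delay with [screen_repeats()], and reports the per-delay mean and SD of
#' the initial rates over the kept repeats.
#'
#' @param traces Data frame with columns `delay_s`, `rep` (repeat id),
#'   `time_s`, `fluorescence` (and optionally `condition`, which must be
#'   single-valued).
#' @param t_eval Rate evaluation time in seconds (default 0.002).
#' @param mad_mult,rmse_mult Outlier-screen thresholds (see
#'   [screen_repeats()]).
#' @return Data frame of class `rate_course` with columns `delay_s`,
#'   `k_mean`, `k_sd`, `n_used`, `n_rejected`.
#' @export
aggregate_rates <- function(traces, t_eval = 0.002, mad_mult = 3,
                            rmse_mult = 3) {
  stopifnot(is.data.frame(traces),
            all(c("delay_s", "rep", "time_s", "fluorescence") %in% names(traces)))
  if ("condition" %in% names(traces) && length(unique(traces$condition)) > 1L)
    stop("aggregate_rates expects a single condition; split the data first")
  delays <- sort(unique(traces$delay_s))
  rows <- lapply(delays, function(d) {
    sub <- traces[traces$delay_s == d, ]
    fits <- lapply(split(sub, sub$rep), function(tr)
      fit_stretched(tr$time_s, tr$fluorescence))
    scr <- screen_repeats(fits, t_eval = t_eval, mad_mult = mad_mult,
                          rmse_mult = rmse_mult)
    kept <- scr$rates[scr$kept]
    data.frame(delay_s = d, k_mean = mean(kept),
               k_sd = if (length(kept) > 1L) stats::sd(kept) else 0,
               n_used = length(scr$kept), n_rejected = length(scr$rejected))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_course", "data.frame")
  out
}

#' Decompose the rate-versus-delay course into activation and desensitization
#'
#' Fits the mean Tl+ influx rate as a function of the agonist pre-incubation
#' delay with a double exponential,
#' K(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2) (signed amplitudes; the
#' rise-then-decay course makes one amplitude negative). Components are
#' canonically ordered tau1 < tau2: the fast component describes activation
#' and the slow component desensitization. If no second component is
#' resolvable the fit falls back to a single exponential and is flagged.
#'
#' @param points A `rate_course` data frame (from [aggregate_rates()]) or any
#'   data frame with columns `delay_s` and `k_mean`; >= 5 delay points.
#' @param offset If `TRUE`, add a constant baseline term to absorb
#'   delay-independent leak flux (default `FALSE`, the offset-free form).
#' @return An object of class `rate_course_fit`: list with `A1`, `A2`,
#'   `tau1`, `tau2` (s, tau1 < tau2), `offset`, `model`
#'   (`"double"`/`"single"`), `rmse`.
#' @export
fit_rate_course <- function(points, offset = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("delay_s", "k_mean") %in% names(points)))
  t <- as.numeric(points$delay_s); k <- as.numeric(points$k_mean)
  if (length(t) < 5L) stop("need >= 5 delay points spanning rise and decay")
  ord <- order(t); t <- t[ord]; k <- k[ord]

  kmax <- max(k); tpk <- t[which.max(k)]
  starts <- list()
  for (f1 in c(0.3, 1)) for (f2 in c(3, 10, 30)) {
    starts[[length(starts) + 1L]] <-
      list(A1 = -kmax, tau1 = max(f1 * tpk, min(t)), A2 = kmax,
           tau2 = min(f2 * tpk, max(t)))
  }
  best <- NULL
  for (st in starts) {
    fml <- if (offset)
      k ~ C + A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    else
      k ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    st2 <- if (offset) c(st, list(C = min(k))) else st
    lw <- c(A1 = -Inf, tau1 = 1e-6, A2 = -Inf, tau2 = 1e-6)
    up <- c(A1 = Inf, tau1 = 1e6, A2 = Inf, tau2 = 1e6)
    if (offset) { lw <- c(lw, C = -Inf); up <- c(up, C = Inf) }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, start = st2, lower = lw[names(st2)],
                        upper = up[names(st2)],
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(stats::resid(fit)^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
  }
  single <- function() {
    # monotone course: single-component fallback
    fit1 <- tryCatch(
      minpack.lm::nlsLM(k ~ A * exp(-t / tau),
                        start = list(A = kmax, tau = stats::median(t)),
                        lower = c(A = -Inf, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) stop("rate-course fit failed in both forms"))
    cf <- stats::coef(fit1)
    structure(list(A1 = cf[["A"]], A2 = NA_real_, tau1 = cf[["tau"]],
                   tau2 = NA_real_, offset = 0, model = "single",
                   rmse = sqrt(mean(stats::resid(fit1)^2))),
              class = "rate_course_fit")
  }
  if (is.null(best)) return(single())
  cf <- stats::coef(best$fit)
  tau1 <- cf[["tau1"]]; tau2 <- cf[["tau2"]]
  A1 <- cf[["A1"]]; A2 <- cf[["A2"]]
  if (tau1 > tau2) { tmp <- tau1; tau1 <- tau2; tau2 <- tmp
                     tmp <- A1; A1 <- A2; A2 <- tmp }
  # unresolvable second component: indistinguishable taus or vanishing amplitude
  if (tau2 / tau1 < 1.05 || abs(A2) < 1e-6 * max(abs(A1), 1e-12) ||
      abs(A1) < 1e-6 * max(abs(A2), 1e-12))
    return(single())
  structure(list(A1 = A1, A2 = A2, tau1 = tau1, tau2 = tau2,
                 offset = if (offset) cf[["C"]] else 0, model = "double",
                 rmse = sqrt(mean(stats::resid(best$fit)^2))),
            class = "rate_course_fit")
}

#' @export
print.rate_course_fit <- function(x, ...) {
  if (x$model == "single")
    cat(sprintf("<rate_course_fit> single component: A = %.3g, tau = %.4g s\n",
                x$A1, x$tau1))
  else
    cat(sprintf(paste0("<rate_course_fit> activation tau1 = %.4g s (A1 = %.3g), ",
                       "desensitization tau2 = %.4g s (A2 = %.3g)\n"),
                x$tau1, x$A1, x$tau2, x$A2))
  invisible(x)
}

#' @export
coef.rate_course_fit <- function(object, ...) {
  c(A1 = object$A1, tau1 = object$tau1, A2 = object$A2, tau2 = object$tau2,
    offset = object$offset)
}

#' Full stopped-flow flux pipeline
#'
#' Runs the complete sequential-mixing analysis on a table of quench traces
#' for one condition: stretched-exponential fit of every repeat, initial
#' rates at `t_eval`, outlier screening, per-delay aggregation, and
#' double-exponential decomposition of the rate-versus-delay course.
#'
#' @inheritParams aggregate_rates
#' @inheritParams fit_rate_course
#' @return List with `rates` (the `rate_course` table) and `fit` (the
#'   `rate_course_fit`).
#' @export
flux_pipeline <- function(traces, t_eval = 0.002, mad_mult = 3,
                          rmse_mult = 3, offset = FALSE) {
  rates <- aggregate_rates(traces, t_eval = t_eval, mad_mult = mad_mult,
                           rmse_mult = rmse_mult)
  list(rates = rates, fit = fit_rate_course(rates, offset = offset))
}
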