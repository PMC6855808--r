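#' Activation time constant of an agonist-evoked current
#'
#' Fits a single exponential, I(t) = A (1 - exp(-t/tau)), to the 10-90% rise
#' window between agonist onset (t = 0) and the peak current.
#'
#' @param time Times in seconds; agonist application at t = 0.
#' @param current Currents in pA (peak taken as the maximum after onset).
#' @return List with `tau` (s), `rmse`, and logical `flagged` (TRUE when the
#'   rise is faster than the sampling can resolve; `tau` is then bounded by
#'   the sample interval).
#' @export
fit_activation <- function(time, current) {
  time <- as.numeric(time); current <- as.numeric(current)
  on <- time >= 0
  t <- time[on]; i <- current[on]
  if (length(t) < 5L) stop("fit failure: too few samples after agonist onset")
  pk <- which.max(i)
  if (pk <= 1L || i[pk] <= 0) stop("fit failure: no discernible peak")
  ipk <- i[pk]
  dt <- stats::median(diff(t))
  # 10-90% rise window
  w <- which(i[1:pk] >= 0.1 * ipk & i[1:pk] <= 0.9 * ipk)
  if (length(w) < 4L) {
    return(list(tau = dt, rmse = NA_real_, flagged = TRUE))
  }
  tw <- t[w]; iw <- i[w]
  t63 <- tw[which.min(abs(iw - 0.632 * ipk))]
  tau0 <- max(t63, dt)
  fit <- tryCatch(
    minpack.lm::nlsLM(iw ~ A * (1 - exp(-tw / tau)),
                      start = list(A = ipk, tau = tau0),
                      lower = c(A = 0, tau = dt / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("fit failure: activation fit did not converge"))
  cf <- stats::coef(fit)
  list(tau = cf[["tau"]], rmse = sqrt(mean(stats::resid(fit)^2)),
       flagged = FALSE)
}

#' Fit the desensitization decay with single and double exponentials
#'
#' From the peak sample onward the current is fitted to both
#' I(t) = C + A exp(-(t - t_pk)/tau) and
#' I(t) = C + A1 exp(-(t - t_pk)/tau1) + A2 exp(-(t - t_pk)/tau2)
#' (free plateau C; currents decay to a non-zero level). The model is
#' selected by the small-sample-corrected Akaike information criterion;
#' both scores are retained.
#'
#' @param time Times in seconds (agonist at t = 0).
#' @param current Currents in pA.
#' @return An object of class `desens_fit`: list with `model`
#'   (`"single"`/`"double"`), `components` (data frame of `amplitude`,
#'   `tau`), `plateau`, `aicc` (named, both models), `rmse`.
#' @export
fit_desensitization <- function(time, current) {
  time <- as.numeric(time); current <- as.numeric(current)
  on <- time >= 0
  t <- time[on]; i <- current[on]
  pk <- which.max(i)
  if (pk >= length(t) - 5L) stop("fit failure: no decay phase after the peak")
  s <- t[pk:length(t)] - t[pk]
  y <- i[pk:length(i)]
  if (y[1] <= utils::tail(y, 1L) + 1e-12 * max(abs(y)))
    stop("fit failure: trace does not decay after the peak")
  n <- length(y)
  plateau0 <- mean(utils::tail(y, max(3L, n %/% 20L)))
  amp0 <- y[1] - plateau0
  t63 <- s[which.min(abs(y - (plateau0 + amp0 * exp(-1))))]
  tau0 <- max(t63, diff(range(s)) / 100)

  aicc <- function(fit, k) {
    rss <- sum(stats::resid(fit)^2)
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  f1 <- tryCatch(
    minpack.lm::nlsLM(y ~ C + A * exp(-s / tau),
                      start = list(C = plateau0, A = amp0, tau = tau0),
                      lower = c(C = -Inf, A = 0, tau = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  f2 <- tryCatch(
    minpack.lm::nlsLM(y ~ C + A1 * exp(-s / tau1) + A2 * exp(-s / tau2),
                      start = list(C = plateau0, A1 = 0.6 * amp0,
                                   tau1 = tau0 / 4, A2 = 0.4 * amp0,
                                   tau2 = tau0 * 4),
                      lower = c(C = -Inf, A1 = 0, tau1 = 1e-8, A2 = 0,
                                tau2 = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  if (is.null(f1) && is.null(f2)) stop("fit failure: decay fits did not converge")
  a1 <- if (!is.null(f1)) aicc(f1, 4L) else Inf  # C, A, tau + sigma
  a2 <- if (!is.null(f2)) aicc(f2, 6L) else Inf
  use_double <- FALSE
  if (!is.null(f2)) {
    cf2 <- stats::coef(f2)
    taus_distinct <- max(cf2[["tau1"]], cf2[["tau2"]]) /
      min(cf2[["tau1"]], cf2[["tau2"]]) > 1.05
    both_present <- min(cf2[["A1"]], cf2[["A2"]]) >
      1e-3 * (cf2[["A1"]] + cf2[["A2"]])
    use_double <- (a2 < a1) && taus_distinct && both_present
  }
  if (use_double) {
    cf <- stats::coef(f2)
    comp <- data.frame(amplitude = c(cf[["A1"]], cf[["A2"]]),
                       tau = c(cf[["tau1"]], cf[["tau2"]]))
    comp <- comp[order(comp$tau), ]
    rownames(comp) <- NULL
    structure(list(model = "double", components = comp, plateau = cf[["C"]],
                   aicc = c(single = a1, double = a2),
                   rmse = sqrt(mean(stats::resid(f2)^2))),
              class = "desens_fit")
  } else {
    cf <- stats::coef(f1)
    structure(list(model = "single",
                   components = data.frame(amplitude = cf[["A"]],
                                           tau = cf[["tau"]]),
                   plateau = cf[["C"]], aicc = c(single = a1, double = a2),
                   rmse = sqrt(mean(stats::resid(f1)^2))),
              class = "desens_fit")
  }
}

#' @export
print.desens_fit <- function(x, ...) {
  cat(sprintf("<desens_fit> %s exponential, weighted tau = %.4g s, plateau = %.3g\n",
              x$model, weighted_tau(x), x$plateau))
  invisible(x)
}

#' Amplitude-weighted desensitization time constant
#'
#' Single-exponential fits return their tau; double-exponential fits return
#' (A1 tau1 + A2 tau2)/(A1 + A2).
#'
#' @param fit A `desens_fit`, or a list with `components` (amplitude, tau).
#' @return Weighted tau in seconds.
#' @export
weighted_tau <- function(fit) {
  comp <- fit$components
  stopifnot(is.data.frame(comp), all(c("amplitude", "tau") %in% names(comp)))
  if (nrow(comp) == 1L) return(comp$tau)
  if (abs(sum(comp$amplitude)) < 1e-300)
    stop("domain error: amplitudes sum to zero")
  sum(comp$amplitude * comp$tau) / sum(comp$amplitude)
}

#' Extent of desensitization at 20 s
#'
#' Current 20 s after agonist onset normalized to the peak current; 1 means
#' no desensitization, 0 full decay.
#'
#' @param time Times in seconds (agonist at t = 0; must extend to >= 20 s).
#' @param current Currents in pA.
#' @param at Evaluation time in seconds (default 20).
#' @return Fraction of peak current remaining.
#' @export
extent_at_20s <- function(time, current, at = 20) {
  time <- as.numeric(time); current <- as.numeric(current)
  on <- time >= 0
  t <- time[on]; i <- current[on]
  if (max(t) < at)
    stop(sprintf("domain error: trace ends at %.3g s, before %g s", max(t), at))
  pk <- max(i)
  if (pk <= 0) stop("fit failure: no positive peak current")
  stats::approx(t, i, xout = at, ties = "ordered")$y / pk
}

#' Fit the peak-current dose-response with a fixed-slope Hill equation
#'
#' I(c) = I_max c^n / (c^n + EC50^n) with the Hill coefficient fixed
#' (default n = 2).
#'
#' @param concentration Agonist concentrations in mM (>= 4 distinct values).
#' @param peak_current Peak currents (same length).
#' @param hill_n Fixed Hill coefficient (default 2).
#' @return An object of class `dose_fit`: list with `ec50` (mM), `hill_n`,
#'   `i_max`, `rmse`, and logical `wide_confidence` (TRUE when the data do
#'   not reach saturation, i.e. the largest tested concentration is below
#'   the fitted EC50).
#' @export
fit_dose_response <- function(concentration, peak_current, hill_n = 2) {
  cc <- as.numeric(concentration); ii <- as.numeric(peak_current)
  if (length(unique(cc)) < 4L) stop("need >= 4 distinct concentrations")
  imax0 <- max(ii)
  ec0 <- stats::approx(ii, cc, xout = imax0 / 2, ties = mean)$y
  starts <- unique(c(ec0[is.finite(ec0)],
                     stats::quantile(cc, c(0.25, 0.5, 0.75), names = FALSE)))
  fit <- NULL
  for (e0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ii ~ imax * cc^hill_n / (cc^hill_n + ec50^hill_n),
        start = list(imax = imax0, ec50 = e0),
        lower = c(imax = 0, ec50 = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("fit failure: dose-response fit did not converge")
  cf <- stats::coef(fit)
  structure(list(ec50 = cf[["ec50"]], hill_n = hill_n, i_max = cf[["imax"]],
                 rmse = sqrt(mean(stats::resid(fit)^2)),
                 wide_confidence = max(cc) < cf[["ec50"]]),
            class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("<dose_fit> EC50 = %.4g mM (Hill n = %g fixed), I_max = %.4g%s\n",
              x$ec50, x$hill_n, x$i_max,
              if (x$wide_confidence) " [wide confidence: no saturation]" else ""))
  invisible(x)
}

#' @export
coef.dose_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill_n = object$hill_n, i_max = object$i_max)
}

#' Pool weighted time constants across traces
#'
#' Pools the weighted taus of double-exponential fits with the taus of
#' single-exponential fits and reports their mean and SD. With a single
#' observation the SD is reported as 0 and flagged.
#'
#' @param fits List of `desens_fit` objects.
#' @return List with `mean`, `sd`, `n`, and logical `single_obs`.
#' @export
combine_weighted_taus <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  taus <- vapply(fits, weighted_tau, numeric(1))
  list(mean = mean(taus),
       sd = if (length(taus) > 1L) stats::sd(taus) else 0,
       n = length(taus), single_obs = length(taus) == 1L)
}

#' Group comparisons of channel properties
#'
#' `design = "many_vs_many"`: one-way ANOVA with post-hoc Tukey HSD pairwise
#' adjusted p-values. `design = "wt_vs_mutants"`: pairwise Welch t-tests of
#' every group against the reference with Bonferroni-adjusted p-values.
#'
#' @param values Numeric measurements.
#' @param group Group labels (same length; >= 2 groups with n >= 2 each).
#' @param design `"many_vs_many"` or `"wt_vs_mutants"`.
#' @param reference Reference group label for `wt_vs_mutants` (default
#'   `"WT"`).
#' @param alpha Significance level applied after adjustment (default 0.05).
#' @return List with `design`, `anova_F`/`anova_p` (many_vs_many only), and
#'   `table`: data frame of pairwise comparisons with adjusted p-values and
#'   a `significant` flag.
#' @export
group_compare <- function(values, group,
                          design = c("many_vs_many", "wt_vs_mutants"),
                          reference = "WT", alpha = 0.05) {
  design <- match.arg(design)
  values <- as.numeric(values); group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) < 2L)) stop("each group needs n >= 2")
  wvar <- tapply(values, group, stats::var)
  if (all(wvar == 0)) stop("degenerate input: zero within-group variance everywhere")
  if (design == "many_vs_many") {
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    tab <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
    list(design = design, anova_F = an[["F value"]][1],
         anova_p = an[["Pr(>F)"]][1], table = tab)
  } else {
    if (!reference %in% levels(group))
      stop(sprintf("reference group '%s' not found", reference))
    others <- setdiff(levels(group), reference)
    ref_vals <- values[group == reference]
    p <- vapply(others, function(g)
      stats::t.test(values[group == g], ref_vals)$p.value, numeric(1))
    p_adj <- stats::p.adjust(p, method = "bonferroni")
    tab <- data.frame(comparison = paste(others, "vs", reference),
                      p = p, p_adj = p_adj, significant = p_adj < alpha,
                      row.names = NULL)
    list(design = design, table = tab)
  }
}
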