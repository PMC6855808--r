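#' Hill concentration-effect curve
#'
#' Parametric description of the thermal stabilizing effect of a lipid versus
#' its concentration: effect(c) = baseline + (e_max - baseline) *
#' c^n / (c^n + EC50^n). The effect is the ratio of the pentamer peak height
#' after heating with lipid to the heated no-lipid control, so baseline = 1 by
#' definition.
#'
#' @param ec50 Half-effect concentration in uM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param e_max Asymptotic effect (>= baseline).
#' @param baseline Effect at zero lipid (default 1).
#' @return An object of class `hill_fit` (also usable as a plain curve, with
#'   `convergence` fields absent).
#' @export
#' @examples
#' hill_curve(52, 1.7, e_max = 4)
hill_curve <- function(ec50, hill_n, e_max = 1 + 1, baseline = 1) {
  ec50 <- as.numeric(ec50); hill_n <- as.numeric(hill_n)
  if (!is.finite(ec50) || ec50 <= 0) stop("'ec50' must be > 0")
  if (!is.finite(hill_n) || hill_n <= 0) stop("'hill_n' must be > 0")
  if (e_max < baseline) stop("'e_max' must be >= baseline")
  structure(list(ec50 = ec50, hill_n = hill_n, e_max = e_max,
                 baseline = baseline),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g uM, Hill n = %.3g, baseline = %g, e_max = %.4g\n",
              x$ec50, x$hill_n, x$baseline, x$e_max))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill_n = object$hill_n, e_max = object$e_max,
    baseline = object$baseline)
}

#' @export
predict.hill_fit <- function(object, concentration, ...) {
  object$baseline + (object$e_max - object$baseline) *
    fractional_effect(object, concentration)
}

#' Fit the thermal stabilizing effect with a Hill function
#'
#' Least-squares fit of effect(c) = baseline + (e_max - baseline) *
#' c^n / (c^n + EC50^n) with the baseline fixed at 1 (no lipid equals the
#' heated control by construction of the effect ratio); EC50, n and e_max are
#' free.
#'
#' @param data Data frame with columns `concentration` (uM) and `effect`
#'   (ratio >= 0); an optional `replicate` column is ignored by the fit.
#' @param baseline Fixed baseline effect (default 1).
#' @return A `hill_fit` with the fitted parameters and an `rmse` element.
#' @export
#' @examples
#' d <- gen_stability_curve(hill_curve(52, 1.7, e_max = 4),
#'                          c(10, 25, 50, 100, 200, 400), sigma = 0, seed = 1)
#' fit_hill_stability(d)
fit_hill_stability <- function(data, baseline = 1) {
  stopifnot(is.data.frame(data), all(c("concentration", "effect") %in% names(data)))
  conc <- as.numeric(data$concentration); eff <- as.numeric(data$effect)
  if (any(!is.finite(eff)) || any(conc < 0)) stop("invalid stability data")
  if (length(unique(conc)) < 4L)
    stop("fit failure: need >= 4 distinct concentrations")
  if (max(abs(eff - baseline)) < 1e-8 ||
      stats::sd(eff) < 1e-8 * max(1, mean(abs(eff))))
    stop("fit failure: no concentration-dependent signal above baseline")
  e_max0 <- max(eff)
  half <- baseline + (e_max0 - baseline) / 2
  ec50_0 <- tryCatch(stats::approx(eff, conc, xout = half, ties = mean)$y,
                     error = function(e) NA_real_)
  if (!is.finite(ec50_0)) ec50_0 <- stats::median(conc[conc > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      eff ~ baseline + (emax - baseline) * conc^n / (conc^n + ec50^n),
      start = list(emax = e_max0, ec50 = ec50_0, n = 1.5),
      lower = c(emax = baseline, ec50 = 1e-6, n = 0.05),
      upper = c(emax = Inf, ec50 = 1e7, n = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(paste0("fit failure (non-convergence): %s; initial guesses ",
                          "were e_max = %.3g, EC50 = %.3g uM, n = 1.5"),
                   conditionMessage(e), e_max0, ec50_0)))
  cf <- stats::coef(fit)
  out <- hill_curve(cf[["ec50"]], cf[["n"]], e_max = cf[["emax"]],
                    baseline = baseline)
  out$rmse <- sqrt(mean(stats::resid(fit)^2))
  out$n_obs <- length(eff)
  out
}

#' Fractional Hill effect
#'
#' Fraction of the maximal stabilization above baseline reached at a given
#' concentration: c^n / (c^n + EC50^n). Maps EC50 to exactly 0.5.
#'
#' @param curve A `hill_fit` (fitted or constructed with [hill_curve()]).
#' @param concentration Concentration(s) in uM, >= 0.
#' @return Fraction(s) in `[0, 1)`.
#' @export
fractional_effect <- function(curve, concentration) {
  stopifnot(inherits(curve, "hill_fit"))
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("'concentration' must be nonnegative and finite")
  cn <- concentration^curve$hill_n
  cn / (cn + curve$ec50^curve$hill_n)
}

#' Measured lipid-binding curve
#'
#' Average bound-lipid counts versus concentration, as quantified from
#' native-MS peak sets (one point per concentration).
#'
#' @param concentration Strictly increasing concentrations in uM.
#' @param avg_bound Average bound counts (>= 0), same length.
#' @param sd Optional standard deviations (default 0).
#' @param n_replicates Optional replicate counts (default 1).
#' @param species Species label (default "POPG").
#' @return An object of class `binding_curve`.
#' @export
binding_curve <- function(concentration, avg_bound, sd = 0, n_replicates = 1L,
                          species = "POPG") {
  concentration <- as.numeric(concentration); avg_bound <- as.numeric(avg_bound)
  if (length(concentration) != length(avg_bound) || length(concentration) == 0L)
    stop("'concentration' and 'avg_bound' must be nonempty and of equal length")
  if (any(diff(concentration) <= 0))
    stop("'concentration' must be strictly increasing")
  if (any(avg_bound < 0)) stop("'avg_bound' must be >= 0")
  structure(list(species = species, concentration = concentration,
                 avg_bound = avg_bound, sd = rep_len(sd, length(avg_bound)),
                 n_replicates = rep_len(as.integer(n_replicates),
                                        length(avg_bound))),
            class = "binding_curve")
}

#' Couple lipid binding to the thermal stabilizing effect
#'
#' Expresses the fractional stabilizing effect as a function of the number of
#' bound lipids by eliminating concentration between the binding curve and the
#' Hill stability curve: for each queried bound count the (extrapolated)
#' binding curve is inverted for concentration and the fractional Hill effect
#' is evaluated there. Within the measured range the binding curve is
#' interpolated piecewise-linearly through the origin; beyond it,
#' `extrapolation = "linear"` continues the line through the origin and the
#' last measured point, while `extrapolation = "model"` inverts a supplied
#' binomial [binding_model()].
#'
#' @param binding A [binding_curve()] (the origin (0, 0) is implied and need
#'   not be included).
#' @param curve A `hill_fit`.
#' @param n_bound Bound-lipid counts at which to evaluate the coupling.
#' @param extrapolation `"linear"` (default) or `"model"`.
#' @param model A [binding_model()] (required for `extrapolation = "model"`).
#' @return A data frame of class `coupling_curve` with columns `n_bound`,
#'   `concentration` and `fractional_effect`.
#' @export
#' @examples
#' bc <- binding_curve(12, 2.9)
#' hc <- hill_curve(52, 1.7, e_max = 4)
#' couple_binding_to_stability(bc, hc, n_bound = 32)
couple_binding_to_stability <- function(binding, curve, n_bound,
                                        extrapolation = c("linear", "model"),
                                        model = NULL) {
  extrapolation <- match.arg(extrapolation)
  stopifnot(inherits(binding, "binding_curve"), inherits(curve, "hill_fit"))
  n_bound <- as.numeric(n_bound)
  if (any(n_bound < 0)) stop("'n_bound' must be >= 0")
  xb <- c(0, binding$avg_bound)
  xc <- c(0, binding$concentration)
  if (any(diff(xb) <= 0))
    stop("binding curve must be strictly increasing to be invertible")
  last_b <- xb[length(xb)]; last_c <- xc[length(xc)]
  conc <- vapply(n_bound, function(nb) {
    if (nb <= last_b)
      return(stats::approx(xb, xc, xout = nb, ties = "ordered")$y)
    if (extrapolation == "linear") {
      # continue the line through the origin and the last measured point
      return(nb * last_c / last_b)
    }
    if (is.null(model)) stop("extrapolation = 'model' requires a binding_model")
    if (nb >= model$n_sites)
      stop(sprintf("n_bound = %g is not reachable: the %d-site model saturates below it",
                   nb, model$n_sites))
    p <- nb / model$n_sites
    model$k_d * p / (1 - p)
  }, numeric(1))
  out <- data.frame(n_bound = n_bound, concentration = conc,
                    fractional_effect = fractional_effect(curve, conc))
  class(out) <- c("coupling_curve", "data.frame")
  out
}
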