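#' Lipid species descriptor
#'
#' Small record describing a phospholipid species as it appears in native-MS
#' titrations: a short label (e.g. "POPG"), its headgroup charge class and,
#' optionally, an average mass (the phospholipids handled here are ~750 Da).
#'
#' @param name Short species label, e.g. `"POPG"`.
#' @param charge_class `"anionic"` or `"zwitterionic"`.
#' @param average_mass Optional average mass in Da (must be positive).
#' @return An object of class `lipid_species`.
#' @export
#' @examples
#' lipid_species("POPG", "anionic", 749)
lipid_species <- function(name, charge_class = c("anionic", "zwitterionic"),
                          average_mass = NULL) {
  charge_class <- match.arg(charge_class)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a nonempty string")
  if (!is.null(average_mass)) {
    average_mass <- as.numeric(average_mass)
    if (!is.finite(average_mass) || average_mass <= 0)
      stop("'average_mass' must be a positive number")
  }
  structure(list(name = name, charge_class = charge_class,
                 average_mass = average_mass),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s (%s)\n", x$name, x$charge_class))
  invisible(x)
}

#' Deconvoluted native-MS peak set at one lipid concentration
#'
#' Holds the deconvoluted peak heights of the channel with `n` bound lipids at
#' a single lipid concentration. Peak heights are arbitrary-unit intensities
#' from upstream spectral deconvolution; no isotope or adduct correction is
#' applied here.
#'
#' @param species A [lipid_species()] or a species name (coerced, anionic by
#'   default only when the name is "POPG", otherwise zwitterionic).
#' @param concentration Lipid concentration in uM (>= 0).
#' @param n_bound Integer vector of bound-lipid counts, strictly increasing,
#'   nonnegative, no duplicates.
#' @param intensity Nonnegative finite intensities, same length as `n_bound`,
#'   at least one positive.
#' @param charge_state_max Optional provenance: largest charge state retained
#'   by the upstream deconvolution.
#' @return An object of class `peak_set`.
#' @export
#' @examples
#' peak_set("POPG", 12, n_bound = 0:2, intensity = c(2, 1, 1))
peak_set <- function(species, concentration, n_bound, intensity,
                     charge_state_max = NULL) {
  if (is.character(species))
    species <- lipid_species(species,
                             if (identical(species, "POPG")) "anionic" else "zwitterionic")
  stopifnot(inherits(species, "lipid_species"))
  concentration <- as.numeric(concentration)
  if (length(concentration) != 1L || !is.finite(concentration) || concentration < 0)
    stop("'concentration' must be a single nonnegative number (uM)")
  n_bound <- as.integer(n_bound)
  intensity <- as.numeric(intensity)
  if (length(n_bound) != length(intensity) || length(n_bound) == 0L)
    stop("'n_bound' and 'intensity' must be nonempty and of equal length")
  if (any(n_bound < 0L)) stop("'n_bound' must be nonnegative")
  if (any(diff(n_bound) <= 0L))
    stop("'n_bound' must be strictly increasing with no duplicates")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (all(intensity == 0))
    stop("degenerate peak set: all intensities are zero")
  structure(list(species = species, concentration = concentration,
                 n_bound = n_bound, intensity = intensity,
                 charge_state_max = charge_state_max),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s at %g uM: %d peaks (n = %d..%d), average bound %.3g\n",
              x$species$name, x$concentration, length(x$n_bound),
              min(x$n_bound), max(x$n_bound), average_bound(x)))
  invisible(x)
}

#' Average number of bound lipids from a peak set
#'
#' Intensity-weighted mean bound-lipid count,
#' \eqn{\sum_n n I_n / \sum_n I_n}, where \eqn{I_n} is the deconvoluted peak
#' height of the complex with \eqn{n} bound lipids.
#'
#' @param peaks A [peak_set()].
#' @return The average number of bound lipids (between 0 and `max(n_bound)`).
#' @export
#' @examples
#' average_bound(peak_set("POPG", 12, 0:2, c(2, 1, 1)))  # 0.75
average_bound <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  s <- sum(peaks$intensity)
  if (s <= 0) stop("degenerate peak set: all intensities are zero")
  sum(peaks$n_bound * peaks$intensity) / s
}

#' Binomial equal-affinity site model
#'
#' Model with `n_sites` equivalent, independent lipid sites, each with
#' dissociation constant `k_d` (uM). The per-site occupancy at free lipid
#' concentration \eqn{[A]} is \eqn{p = [A]/([A]+K)} and the number of occupied
#' sites is binomially distributed.
#'
#' @param n_sites Integer number of sites N >= 1.
#' @param k_d Dissociation constant K in uM (> 0, finite).
#' @return An object of class `binding_model`.
#' @export
#' @examples
#' binding_model(32, 120.4)
binding_model <- function(n_sites, k_d) {
  if (length(n_sites) != 1L || n_sites < 1 || n_sites != round(n_sites))
    stop("'n_sites' must be a single integer >= 1")
  k_d <- as.numeric(k_d)
  if (length(k_d) != 1L || !is.finite(k_d) || k_d <= 0)
    stop("'k_d' must be a single finite positive number (uM)")
  structure(list(n_sites = as.integer(n_sites), k_d = k_d),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> N = %d equivalent sites, K = %g uM\n",
              x$n_sites, x$k_d))
  invisible(x)
}

#' Per-site occupancy probability
#'
#' @param model A [binding_model()].
#' @param concentration Lipid concentration(s) in uM, >= 0.
#' @return Occupancy probability p = c/(c + K) in `[0, 1)`.
#' @export
occupancy <- function(model, concentration) {
  stopifnot(inherits(model, "binding_model"))
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("'concentration' must be nonnegative and finite")
  concentration / (concentration + model$k_d)
}

#' Mole-fraction distribution over bound-lipid counts
#'
#' Binomial distribution of the number of occupied sites q = 0..N at the given
#' concentration: \eqn{B(q) = \binom{N}{q} p^q (1-p)^{N-q}}.
#'
#' @param model A [binding_model()].
#' @param concentration Concentration in uM.
#' @return Numeric vector of length N + 1 summing to 1; element `q + 1` is the
#'   mole fraction of the q-bound species.
#' @export
bound_distribution <- function(model, concentration) {
  p <- occupancy(model, concentration)
  stopifnot(length(p) == 1L)
  stats::dbinom(0:model$n_sites, size = model$n_sites, prob = p)
}

#' Expected number of bound lipids
#'
#' Mean of the binomial bound distribution, N p. Strictly increasing in
#' concentration and decreasing in K.
#'
#' @param model A [binding_model()].
#' @param concentration Concentration(s) in uM.
#' @return Expected bound-lipid count(s) N c/(c + K).
#' @export
expected_bound <- function(model, concentration) {
  model$n_sites * occupancy(model, concentration)
}

# Joint SSR between observed per-concentration mole fractions and binomial
# predictions; each peak set is normalized to unit total intensity and
# concentrations are weighted equally.
.binding_ssr <- function(peaksets, n_sites, k_d, fitted_on) {
  model <- binding_model(n_sites, k_d)
  if (fitted_on == "avg_bound") {
    obs <- vapply(peaksets, average_bound, numeric(1))
    pred <- vapply(peaksets, function(ps) expected_bound(model, ps$concentration),
                   numeric(1))
    return(sum((obs - pred)^2))
  }
  ssr <- 0
  for (ps in peaksets) {
    frac <- ps$intensity / sum(ps$intensity)
    q <- ps$n_bound
    p <- occupancy(model, ps$concentration)
    pred <- ifelse(q > model$n_sites, 0,
                   stats::dbinom(pmin(q, model$n_sites), model$n_sites, p))
    ssr <- ssr + sum((frac - pred)^2)
  }
  ssr
}

#' Fit the binomial site model across a concentration series
#'
#' Jointly fits deconvoluted peak sets measured at several concentrations to
#' the equal-affinity binomial model, minimizing the summed squared residuals
#' between observed mole fractions (each peak set normalized to unit total
#' intensity) and the binomial predictions. One parameter is varied per call:
#' either K with the site count fixed (`mode = "fit_K"`) or the integer site
#' count with K fixed (`mode = "fit_N"`, grid search over `1:n_max`).
#'
#' @param peaksets List of [peak_set()] objects at >= 2 distinct
#'   concentrations.
#' @param mode `"fit_K"` (vary K, N fixed) or `"fit_N"` (vary N, K fixed).
#' @param n_sites Fixed site count for `mode = "fit_K"`.
#' @param k_d Fixed dissociation constant (uM) for `mode = "fit_N"`.
#' @param fitted_on Objective data: `"mole_fractions"` (default) or
#'   `"avg_bound"` (average-bound curve).
#' @param n_max Upper end of the integer grid for `fit_N` (default 64).
#' @return An object of class `binding_fit` with elements `model`
#'   ([binding_model()]), `mode`, `objective` (minimized SSR), `fitted_on`,
#'   and `concentrations`.
#' @export
#' @examples
#' m <- binding_model(32, 120)
#' ps <- gen_peaksets(m, c(5, 12, 24, 36), sigma = 0, seed = 1)
#' fit_binding(ps, mode = "fit_K", n_sites = 32)
fit_binding <- function(peaksets, mode = c("fit_K", "fit_N"),
                        n_sites = NULL, k_d = NULL,
                        fitted_on = c("mole_fractions", "avg_bound"),
                        n_max = 64L) {
  mode <- match.arg(mode)
  fitted_on <- match.arg(fitted_on)
  if (!is.list(peaksets) || !all(vapply(peaksets, inherits, logical(1), "peak_set")))
    stop("'peaksets' must be a list of peak_set objects")
  concs <- vapply(peaksets, function(ps) ps$concentration, numeric(1))
  if (length(unique(concs)) < 2L)
    stop("fit failure: need peak sets at >= 2 distinct concentrations to identify the model")
  if (all(vapply(peaksets, function(ps) all(ps$n_bound[ps$intensity > 0] == 0L),
                 logical(1))))
    stop("fit failure: all peak sets are apo-only; binding is unidentifiable")

  if (mode == "fit_K") {
    if (is.null(n_sites)) stop("mode 'fit_K' requires a fixed 'n_sites'")
    obj <- function(logk) .binding_ssr(peaksets, n_sites, exp(logk), fitted_on)
    # the SSR plateaus far from the optimum: coarse log-grid scan, then refine
    grid_k <- seq(log(1e-4), log(1e7), length.out = 241L)
    ssr_k <- vapply(grid_k, obj, numeric(1))
    i <- which.min(ssr_k)
    lo <- grid_k[max(i - 1L, 1L)]; hi <- grid_k[min(i + 1L, length(grid_k))]
    opt <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-10)
    model <- binding_model(n_sites, exp(opt$minimum))
    objective <- opt$objective
  } else {
    if (is.null(k_d)) stop("mode 'fit_N' requires a fixed 'k_d'")
    grid <- seq_len(n_max)
    ssr <- vapply(grid, function(n) .binding_ssr(peaksets, n, k_d, fitted_on),
                  numeric(1))
    n_best <- grid[which.min(ssr)]
    model <- binding_model(n_best, k_d)
    objective <- min(ssr)
  }
  structure(list(model = model, mode = mode, objective = objective,
                 fitted_on = fitted_on, concentrations = sort(unique(concs)),
                 species = peaksets[[1]]$species$name),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s, mode %s (%s): N = %d, K = %.4g uM, SSR = %.3g\n",
              x$species, x$mode, x$fitted_on, x$model$n_sites, x$model$k_d,
              x$objective))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(n_sites = object$model$n_sites, k_d = object$model$k_d)
}

#' Predict from a binomial binding fit
#'
#' @param object A `binding_fit`.
#' @param concentration Concentration(s) in uM.
#' @param type `"avg_bound"` for the expected bound count, or
#'   `"distribution"` for the mole-fraction vector(s) over q = 0..N.
#' @param ... Unused.
#' @return Numeric vector (avg_bound) or a matrix with one row per
#'   concentration (distribution).
#' @export
predict.binding_fit <- function(object, concentration,
                                type = c("avg_bound", "distribution"), ...) {
  type <- match.arg(type)
  if (type == "avg_bound") return(expected_bound(object$model, concentration))
  t(vapply(concentration, function(cc) bound_distribution(object$model, cc),
           numeric(object$model$n_sites + 1L)))
}

#' Affinity ratio between two fitted species
#'
#' Ratio K_b / K_a of the dissociation constants of two `fit_K` fits with the
#' same site count; a ratio > 1 means species a binds tighter.
#'
#' @param fit_a,fit_b `binding_fit` objects in `fit_K` mode with equal N.
#' @return K_b / K_a.
#' @export
affinity_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "binding_fit"), inherits(fit_b, "binding_fit"))
  if (fit_a$mode != "fit_K" || fit_b$mode != "fit_K")
    stop("affinity_ratio requires both fits in 'fit_K' mode")
  if (fit_a$model$n_sites != fit_b$model$n_sites)
    stop("fits are not comparable: different site counts")
  fit_b$model$k_d / fit_a$model$k_d
}

#' Collapse per-charge-state peaks into a peak set
#'
#' Drops charge states above `max_charge` (the upstream deconvolution was
#' restricted to low charge states where bound-lipid counts are unbiased) and
#' sums the remaining intensities per bound-lipid count.
#'
#' @param raw_peaks Data frame with columns `charge`, `n_bound`, `intensity`,
#'   and optionally `species` and `concentration_uM` (each with a single
#'   unique value).
#' @param max_charge Largest retained charge state (default 26).
#' @param species,concentration Overrides for the species label and
#'   concentration (used when the table lacks those columns).
#' @return A [peak_set()] with `charge_state_max` recorded.
#' @export
filter_charge_states <- function(raw_peaks, max_charge = 26L,
                                 species = NULL, concentration = NULL) {
  need <- c("charge", "n_bound", "intensity")
  if (!all(need %in% names(raw_peaks)))
    stop("'raw_peaks' must have columns charge, n_bound, intensity")
  keep <- raw_peaks[raw_peaks$charge <= max_charge, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("degenerate input: no peaks remain after the charge-state filter")
  agg <- stats::aggregate(intensity ~ n_bound, data = keep, FUN = sum)
  agg <- agg[order(agg$n_bound), ]
  if (is.null(species))
    species <- if ("species" %in% names(keep)) unique(keep$species) else "lipid"
  if (is.null(concentration))
    concentration <- if ("concentration_uM" %in% names(keep))
      unique(keep$concentration_uM) else NA_real_
  if (length(species) != 1L || length(concentration) != 1L || is.na(concentration))
    stop("species and concentration must be single values (supply them explicitly)")
  peak_set(species, concentration, agg$n_bound, agg$intensity,
           charge_state_max = max_charge)
}
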