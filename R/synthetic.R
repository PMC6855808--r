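#' Synthetic native-MS peak sets from a binomial binding model
#'
#' Generates one deconvoluted peak set per concentration: intensities are the
#' binomial mole fractions scaled to `scale` with multiplicative log-normal
#' noise (peak heights are positive and heteroscedastic), truncated at the
#' largest bound count whose exact mole fraction exceeds `1e-4`.
#'
#' @param model A [binding_model()].
#' @param concentrations Concentrations in uM.
#' @param sigma Log-normal sdlog of the multiplicative intensity noise.
#' @param seed Integer seed (the generator is a pure function of its
#'   arguments).
#' @param scale Intensity scale of the unit mole fraction (default 1000).
#' @param species Species label (default "POPG").
#' @return List of [peak_set()] objects with the generating model attached as
#'   attribute `ground_truth`.
#' @export
gen_peaksets <- function(model, concentrations, sigma = 0.05, seed = 1L,
                         scale = 1000, species = "POPG") {
  stopifnot(inherits(model, "binding_model"), sigma >= 0)
  set.seed(seed)
  out <- lapply(concentrations, function(cc) {
    frac <- bound_distribution(model, cc)
    qmax <- max(which(frac > 1e-4)) - 1L
    q <- 0:qmax
    noise <- if (sigma > 0) stats::rlnorm(length(q), 0, sigma) else rep(1, length(q))
    peak_set(species, cc, q, frac[q + 1L] * scale * noise)
  })
  attr(out, "ground_truth") <- list(n_sites = model$n_sites, k_d = model$k_d,
                                    sigma = sigma, seed = seed)
  out
}

#' Synthetic thermal-stability measurements from a Hill curve
#'
#' Effect values are the Hill evaluation plus additive Gaussian noise,
#' floored at 0.
#'
#' @param hill A `hill_fit` / [hill_curve()].
#' @param concentrations Concentrations in uM.
#' @param sigma Additive Gaussian noise SD (effect units).
#' @param seed Integer seed.
#' @param replicates Replicates per concentration (default 1).
#' @return Data frame with columns `concentration`, `effect`, `replicate`;
#'   ground truth attached as attribute `ground_truth`.
#' @export
gen_stability_curve <- function(hill, concentrations, sigma = 0, seed = 1L,
                                replicates = 1L) {
  stopifnot(inherits(hill, "hill_fit"), sigma >= 0)
  set.seed(seed)
  cc <- rep(concentrations, each = replicates)
  eff <- stats::predict(hill, cc)
  if (sigma > 0) eff <- pmax(eff + stats::rnorm(length(cc), 0, sigma), 0)
  out <- data.frame(concentration = cc, effect = eff,
                    replicate = rep(seq_len(replicates),
                                    times = length(concentrations)))
  attr(out, "ground_truth") <- list(ec50 = hill$ec50, hill_n = hill$hill_n,
                                    e_max = hill$e_max, sigma = sigma,
                                    seed = seed)
  out
}

#' Synthetic coarse-grained membrane frames around a pentameric footprint
#'
#' Builds 2-D-per-leaflet frames: the protein transmembrane domain is a ring
#' of TMD beads of radius `protein_radius` at the box center, replicated at
#' both leaflet planes, and each lipid is a single phosphate bead placed
#' uniformly in its leaflet plane outside the protein footprint. Inside the
#' boundary shell (within `cutoff` of a protein bead) species are drawn with
#' probability proportional to `bias * composition`; elsewhere with the bulk
#' composition. The exact expected enrichment,
#' B_i = w_i / sum_j(w_j x_j) - 1, is attached as ground truth.
#'
#' @param composition Named mole fractions summing to 1, e.g.
#'   `c(POPG = 0.1, POPC = 0.9)`.
#' @param n_lipids Total lipids per frame (default 3000, split evenly
#'   between leaflets).
#' @param protein_radius Ring radius in Angstrom (default 22; at the default
#'   lipid density the 6-Angstrom shell then holds ~32 boundary lipids,
#'   the annular census of the pentameric footprint).
#' @param bias Named positive placement weights `w_i` (default all 1 =
#'   unbiased mixing).
#' @param n_frames Number of independent frames.
#' @param box Periodic box lengths in Angstrom (default `c(300, 300)`).
#' @param seed Integer seed.
#' @param cutoff Boundary-shell cutoff in Angstrom (default 6).
#' @param n_ring_beads Protein beads per leaflet ring (default 72).
#' @param leaflet_z Half-spacing of the leaflet planes in Angstrom
#'   (default 17).
#' @return List of [membrane_frame()] objects with attribute `ground_truth`
#'   (named vector `expected_B`).
#' @export
gen_membrane_frames <- function(composition, n_lipids = 3000L,
                                protein_radius = 22, bias = NULL,
                                n_frames = 1L, box = c(300, 300), seed = 1L,
                                cutoff = 6, n_ring_beads = 72L,
                                leaflet_z = 17) {
  stopifnot(abs(sum(composition) - 1) < 1e-8, all(composition > 0),
            !is.null(names(composition)))
  if (is.null(bias)) bias <- stats::setNames(rep(1, length(composition)),
                                             names(composition))
  bias <- bias[names(composition)]
  stopifnot(all(bias > 0))
  set.seed(seed)
  species <- names(composition)
  expected_B <- bias / sum(bias * composition) - 1
  ctr <- box[1:2] / 2
  ang <- seq(0, 2 * pi, length.out = n_ring_beads + 1L)[-1L]
  ring <- data.frame(x = ctr[1] + protein_radius * cos(ang),
                     y = ctr[2] + protein_radius * sin(ang))
  protein <- data.frame(x = rep(ring$x, 2), y = rep(ring$y, 2),
                        z = rep(c(leaflet_z, -leaflet_z),
                                each = n_ring_beads),
                        tmd = TRUE)
  n_leaf <- c(ceiling(n_lipids / 2), floor(n_lipids / 2))
  shell_r <- protein_radius + cutoff
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    lip <- list(); id0 <- 0L
    for (li in 1:2) {
      n <- n_leaf[li]
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(pts) < n) {
        tries <- tries + 1L
        if (tries > 200L) stop("placement error: box too dense for the footprint")
        cand <- cbind(stats::runif(2L * n, 0, box[1]),
                      stats::runif(2L * n, 0, box[2]))
        r <- sqrt((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
        pts <- rbind(pts, cand[r >= protein_radius, , drop = FALSE])
      }
      pts <- pts[seq_len(n), , drop = FALSE]
      r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
      in_shell <- r <= shell_r
      sp <- character(n)
      if (any(in_shell))
        sp[in_shell] <- sample(species, sum(in_shell), replace = TRUE,
                               prob = bias * composition)
      if (any(!in_shell))
        sp[!in_shell] <- sample(species, sum(!in_shell), replace = TRUE,
                                prob = composition)
      lip[[li]] <- data.frame(
        lipid_id = sprintf("L%05d", id0 + seq_len(n)),
        species = sp, bead = "PO4", x = pts[, 1], y = pts[, 2],
        z = if (li == 1L) leaflet_z else -leaflet_z, phosphate = TRUE)
      id0 <- id0 + n
    }
    frames[[f]] <- membrane_frame(protein, do.call(rbind, lip), box = box,
                                  time = f)
  }
  attr(frames, "ground_truth") <- list(expected_B = expected_B,
                                       composition = composition,
                                       bias = bias, seed = seed)
  frames
}

#' Irreversible three-state kinetic scheme for the flux assay
#'
#' Resting -> open (rate `a`) -> desensitized (rate `d`), both irreversible.
#' The open probability after an agonist delay t is
#' O(t) = a/(a - d) (exp(-d t) - exp(-a t)) (confluent limit a t exp(-a t)
#' when a = d), and the target Tl+ influx rate is
#' k(t) = k_leak + k_max O(t).
#'
#' @param a Activation rate in s^-1.
#' @param d Desensitization rate in s^-1 (resolvable components require
#'   a > d > 0).
#' @param k_max Influx rate at full open probability in s^-1 (default 50).
#' @param k_leak Channel-independent leak rate in s^-1 (default 0).
#' @param beta Stretching exponent of the generated quench traces
#'   (default 0.65).
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(a, d, k_max = 50, k_leak = 0, beta = 0.65) {
  stopifnot(a > 0, d > 0, k_max > k_leak, k_leak >= 0,
            beta > 0, beta <= 1)
  structure(list(a = a, d = d, k_max = k_max, k_leak = k_leak, beta = beta),
            class = "kinetic_scheme")
}

#' Open probability of the irreversible scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @param t Delay time(s) in seconds.
#' @return Open probability in `[0, 1]`.
#' @export
open_probability <- function(scheme, t) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  a <- scheme$a; d <- scheme$d
  if (abs(a - d) < 1e-12 * a) return(a * t * exp(-a * t))
  a / (a - d) * (exp(-d * t) - exp(-a * t))
}

# Invert the 2-ms rate formula for tau at fixed beta:
# k = (beta/tau) (t_eval/tau)^(beta-1)  =>  tau = (beta t_eval^(beta-1) / k)^(1/beta)
.tau_from_rate <- function(k, beta, t_eval = 0.002) {
  (beta * t_eval^(beta - 1) / k)^(1 / beta)
}

#' Synthetic sequential-mixing stopped-flow experiment
#'
#' For each agonist-incubation delay, the target influx rate
#' k = k_leak + k_max O(delay) is converted to a stretched-exponential time
#' constant by inverting the 2-ms rate formula at the scheme's beta, and
#' `n_repeats` quench traces are sampled with additive Gaussian noise of SD
#' `sigma` times the quench amplitude. Recovering the scheme from these
#' traces is therefore a true inverse problem for the analysis pipeline.
#'
#' @param scheme A [kinetic_scheme()].
#' @param delays Delays in seconds (default 16 log-spaced points,
#'   10 ms to 25 s).
#' @param n_repeats Repeats per delay (default 8).
#' @param sigma Noise SD as a fraction of the quench amplitude
#'   (default 0.05).
#' @param seed Integer seed.
#' @param times Trace sampling times in seconds (default 150 log-spaced
#'   points over 0.5 ms to 1 s, the recorded quench window).
#' @param f0,f_inf Initial and final fluorescence (defaults 1 and 0.2).
#' @param condition Condition label.
#' @param t_eval Rate evaluation time used in the inversion (default 0.002).
#' @return Data frame with columns `condition`, `delay_s`, `rep`, `time_s`,
#'   `fluorescence`; attribute `ground_truth` holds the scheme, delays and
#'   true per-delay rates.
#' @export
gen_flux_experiment <- function(scheme,
                                delays = exp(seq(log(0.01), log(25),
                                                 length.out = 16L)),
                                n_repeats = 8L, sigma = 0.05, seed = 1L,
                                times = exp(seq(log(5e-4), log(1),
                                                length.out = 150L)),
                                f0 = 1, f_inf = 0.2, condition = "cond",
                                t_eval = 0.002) {
  stopifnot(inherits(scheme, "kinetic_scheme"), sigma >= 0,
            all(delays >= 0.01 - 1e-12), all(delays <= 25 + 1e-9))
  set.seed(seed)
  amp <- f0 - f_inf
  k_true <- scheme$k_leak + scheme$k_max * open_probability(scheme, delays)
  rows <- vector("list", length(delays) * n_repeats)
  idx <- 0L
  for (di in seq_along(delays)) {
    k <- k_true[di]
    ftrace <- if (k > 1e-9) {
      tau <- .tau_from_rate(k, scheme$beta, t_eval)
      f_inf + amp * exp(-(times / tau)^scheme$beta)
    } else rep(f0, length(times))
    for (r in seq_len(n_repeats)) {
      idx <- idx + 1L
      noise <- if (sigma > 0) stats::rnorm(length(times), 0, sigma * amp) else 0
      rows[[idx]] <- data.frame(condition = condition, delay_s = delays[di],
                                rep = r, time_s = times,
                                fluorescence = ftrace + noise)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(scheme = scheme, delays = delays,
                                    k_true = k_true, sigma = sigma,
                                    seed = seed)
  out
}

#' Synthetic agonist-evoked current traces
#'
#' I(t) = peak (1 - exp(-t/tau_act)) (plateau + (1 - plateau)
#' (A1 exp(-t/tau1) + A2 exp(-t/tau2)) / (A1 + A2)) + Gaussian noise,
#' for t >= 0 (agonist onset at t = 0).
#'
#' @param tau_act Activation time constant in seconds.
#' @param desens Named vector `c(A1, tau1, A2, tau2)` of the desensitization
#'   components (set `A2 = 0` for a single-exponential decay).
#' @param plateau Plateau fraction of peak at full desensitization.
#' @param peak Peak current in pA (default 500).
#' @param duration Trace length in seconds (default 25; >= 20 for the
#'   20-s extent).
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param sigma Additive noise SD as a fraction of peak (default 0).
#' @param seed Integer seed.
#' @param n_traces Number of traces (default 1).
#' @param concentration Agonist concentration label in mM (default 30).
#' @param condition Condition label (default "WT").
#' @return Data frame with columns `condition`, `patch_id`,
#'   `concentration_mM`, `time_s`, `current_pA`; ground truth attached as
#'   attribute `ground_truth`.
#' @export
gen_current_traces <- function(tau_act, desens = c(A1 = 1, tau1 = 1.9,
                                                   A2 = 0, tau2 = 10),
                               plateau = 0.1, peak = 500, duration = 25,
                               sample_rate = 1000, sigma = 0, seed = 1L,
                               n_traces = 1L, concentration = 30,
                               condition = "WT") {
  stopifnot(tau_act > 0, plateau >= 0, plateau <= 1, sigma >= 0)
  A1 <- desens[["A1"]]; tau1 <- desens[["tau1"]]
  A2 <- desens[["A2"]]; tau2 <- desens[["tau2"]]
  stopifnot(A1 + A2 > 0, tau1 > 0, tau2 > 0)
  set.seed(seed)
  t <- seq(0, duration, by = 1 / sample_rate)
  decay <- (A1 * exp(-t / tau1) + A2 * exp(-t / tau2)) / (A1 + A2)
  clean <- peak * (1 - exp(-t / tau_act)) * (plateau + (1 - plateau) * decay)
  rows <- lapply(seq_len(n_traces), function(p) {
    noise <- if (sigma > 0) stats::rnorm(length(t), 0, sigma * peak) else 0
    data.frame(condition = condition, patch_id = p,
               concentration_mM = concentration, time_s = t,
               current_pA = clean + noise)
  })
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(tau_act = tau_act, desens = desens,
                                    plateau = plateau, peak = peak,
                                    sigma = sigma, seed = seed)
  out
}
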