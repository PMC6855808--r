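test_that("stretched-exponential fit recovers clean quench parameters", {
  tr <- make_quench_trace(tau = 0.05, beta = 0.7)
  fit <- fit_stretched(tr$time, tr$fluorescence)
  expect_false(fit$no_flux)
  expect_equal(fit$tau, 0.05, tolerance = 1e-3)
  expect_equal(fit$beta, 0.7, tolerance = 1e-3)
  expect_equal(fit$f0, 1, tolerance = 1e-3)
  expect_equal(fit$f_inf, 0.2, tolerance = 1e-3)
  # beta = 1 input reduces to a single exponential
  tr1 <- make_quench_trace(tau = 0.1, beta = 1)
  fit1 <- fit_stretched(tr1$time, tr1$fluorescence)
  expect_equal(fit1$tau, 0.1, tolerance = 1e-3)
  expect_equal(fit1$beta, 1, tolerance = 1e-3)
  # constant trace: no-flux flag, not an error
  flat <- fit_stretched(tr$time, rep(1, length(tr$time)))
  expect_true(flat$no_flux)
  expect_equal(initial_rate(flat), 0)
})

test_that("initial rate follows the 2 ms formula", {
  mk <- function(tau, beta)
    structure(list(tau = tau, beta = beta, no_flux = FALSE),
              class = "stretched_fit")
  expect_equal(initial_rate(mk(0.05, 1)), 1 / 0.05)        # beta = 1: k = 1/tau
  expect_equal(initial_rate(mk(0.002, 0.6)), 0.6 / 0.002)  # t_eval = tau: k = beta/tau
  expect_equal(round(initial_rate(mk(0.1, 0.5)), 2), 35.36)
  # amplitude homogeneity: scaling fluorescence leaves the rate unchanged
  tr <- make_quench_trace(tau = 0.05, beta = 0.7)
  k1 <- initial_rate(fit_stretched(tr$time, tr$fluorescence))
  k2 <- initial_rate(fit_stretched(tr$time, 40 * tr$fluorescence))
  expect_equal(k1, k2, tolerance = 1e-6)
  # continuity in beta near 1
  expect_equal(initial_rate(mk(0.05, 1 - 1e-9)),
               initial_rate(mk(0.05, 1)), tolerance = 1e-6)
})

test_that("repeat screening rejects gross outliers but keeps small panels", {
  mk <- function(tau, rmse = 0.01)
    structure(list(tau = tau, beta = 1, rmse = rmse, no_flux = FALSE),
              class = "stretched_fit")
  same <- replicate(8, mk(0.1), simplify = FALSE)
  expect_length(screen_repeats(same)$rejected, 0)
  # one rate 10x the others among eight
  odd <- c(replicate(7, mk(0.1), simplify = FALSE), list(mk(0.01)))
  scr <- screen_repeats(odd)
  expect_equal(scr$rejected, 8L)
  # high-rmse repeat rejected
  noisy <- c(replicate(7, mk(0.1), simplify = FALSE),
             list(mk(0.1, rmse = 0.2)))
  expect_equal(screen_repeats(noisy)$rejected, 8L)
  # two discordant repeats: both kept with a warning
  expect_warning(out <- screen_repeats(list(mk(0.1), mk(0.01))), "kept")
  expect_length(out$kept, 2)
})

test_that("rate aggregation averages kept repeats per delay", {
  sch <- kinetic_scheme(a = 20, d = 0.5)
  tr <- gen_flux_experiment(sch, delays = c(0.05, 0.2, 1), n_repeats = 4,
                            sigma = 0.03, seed = 5)
  rp <- aggregate_rates(tr)
  expect_equal(nrow(rp), 3)
  expect_true(all(rp$n_used >= 1))
  expect_true(all(rp$k_sd >= 0))
  gt <- attr(tr, "ground_truth")
  expect_equal(rp$k_mean, gt$k_true, tolerance = 0.1)
})

test_that("rate-course decomposition recovers activation and desensitization", {
  # noiseless course at the fast/slow scales of the two lipid conditions
  t <- exp(seq(log(0.01), log(25), length.out = 16))
  k <- -50 * exp(-t / 0.013) + 50 * exp(-t / 9.2)
  fit <- fit_rate_course(data.frame(delay_s = t, k_mean = k))
  expect_equal(fit$model, "double")
  expect_equal(fit$tau1, 0.013, tolerance = 0.01)
  expect_equal(fit$tau2, 9.2, tolerance = 0.01)
  expect_lt(fit$tau1, fit$tau2)
  # single-component input falls back with a flag
  k1 <- 30 * exp(-t / 2)
  fit1 <- fit_rate_course(data.frame(delay_s = t, k_mean = k1))
  expect_equal(fit1$model, "single")
  expect_equal(fit1$tau1, 2, tolerance = 0.01)
  expect_error(fit_rate_course(data.frame(delay_s = t[1:3], k_mean = k[1:3])),
               ">= 5")
})

test_that("three-state open probability drives the recovered time constants", {
  a <- 30; d <- 0.4
  t <- exp(seq(log(0.01), log(25), length.out = 20))
  O <- a / (a - d) * (exp(-d * t) - exp(-a * t))
  fit <- fit_rate_course(data.frame(delay_s = t, k_mean = 50 * O))
  expect_equal(fit$tau1, 1 / a, tolerance = 0.01)
  expect_equal(fit$tau2, 1 / d, tolerance = 0.01)
})

test_that("generator inversion round-trips rates through the stretched fit", {
  sch <- kinetic_scheme(a = 25, d = 0.5, beta = 0.65)
  tr <- gen_flux_experiment(sch, delays = c(0.05, 0.5, 2), n_repeats = 1,
                            sigma = 0, seed = 1)
  gt <- attr(tr, "ground_truth")
  for (i in seq_along(gt$delays)) {
    sub <- tr[tr$delay_s == gt$delays[i], ]
    k_rec <- initial_rate(fit_stretched(sub$time_s, sub$fluorescence))
    expect_equal(k_rec, gt$k_true[i], tolerance = 1e-3)
  }
})

test_that("full pipeline recovers both time constants from a clean experiment", {
  sch <- kinetic_scheme(a = 1 / 0.013, d = 1 / 9.2)
  tr <- gen_flux_experiment(sch, n_repeats = 1, sigma = 0, seed = 1)
  fit <- flux_pipeline(tr)$fit
  expect_equal(fit$tau1, 0.013, tolerance = 0.02)
  expect_equal(fit$tau2, 9.2, tolerance = 0.02)
})

test_that("noisy pipeline recovery stays within 15% for spanning taus", {
  set.seed(77)
  n_exp <- 50
  taus_a <- exp(stats::runif(n_exp, log(0.01), log(0.1)))
  taus_d <- exp(stats::runif(n_exp, log(0.4), log(10)))
  ok <- logical(n_exp)
  for (i in seq_len(n_exp)) {
    sch <- kinetic_scheme(a = 1 / taus_a[i], d = 1 / taus_d[i])
    tr <- gen_flux_experiment(sch, n_repeats = 8, sigma = 0.05,
                              seed = 3000 + i)
    fit <- flux_pipeline(tr)$fit
    ok[i] <- fit$model == "double" &&
      abs(fit$tau1 - taus_a[i]) / taus_a[i] < 0.15 &&
      abs(fit$tau2 - taus_d[i]) / taus_d[i] < 0.15
  }
  expect_gte(mean(ok), 0.90)
})
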