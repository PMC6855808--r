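test_that("activation fit recovers the rise time constant", {
  tr <- gen_current_traces(tau_act = 0.134,
                           desens = c(A1 = 1, tau1 = 1e9, A2 = 0, tau2 = 1e9),
                           plateau = 1, duration = 2, sigma = 0, seed = 1)
  fit <- fit_activation(tr$time_s, tr$current_pA)
  expect_equal(fit$tau, 0.134, tolerance = 0.01)
  expect_false(fit$flagged)
  # near-instantaneous step: tau bounded by the sample interval and flagged
  t <- seq(0, 2, by = 0.001)
  step <- ifelse(t > 0, 100, 0) * exp(-t / 50)
  fs <- fit_activation(t, step)
  expect_true(fs$flagged)
  expect_lte(fs$tau, 0.0011)
  # halving the sample interval leaves tau unchanged within tolerance
  tr2 <- gen_current_traces(tau_act = 0.134,
                            desens = c(A1 = 1, tau1 = 1e9, A2 = 0, tau2 = 1e9),
                            plateau = 1, duration = 2, sample_rate = 2000,
                            sigma = 0, seed = 1)
  fit2 <- fit_activation(tr2$time_s, tr2$current_pA)
  expect_equal(fit2$tau, fit$tau, tolerance = 0.01)
})

test_that("desensitization model selection distinguishes single from double", {
  # generated double decay: taus 0.5 and 5 s, equal amplitudes
  tr <- gen_current_traces(tau_act = 0.01,
                           desens = c(A1 = 1, tau1 = 0.5, A2 = 1, tau2 = 5),
                           plateau = 0.1, duration = 25, sigma = 0, seed = 2)
  fit <- fit_desensitization(tr$time_s, tr$current_pA)
  expect_equal(fit$model, "double")
  expect_equal(fit$components$tau[1], 0.5, tolerance = 0.05)
  expect_equal(fit$components$tau[2], 5, tolerance = 0.05)
  # pure single decay selects the single model
  tr1 <- gen_current_traces(tau_act = 0.01,
                            desens = c(A1 = 1, tau1 = 2, A2 = 0, tau2 = 10),
                            plateau = 0.1, duration = 25, sigma = 0, seed = 3)
  fit1 <- fit_desensitization(tr1$time_s, tr1$current_pA)
  expect_equal(fit1$model, "single")
  expect_equal(fit1$components$tau, 2, tolerance = 0.02)
  # two identical-tau components are unidentifiable: single selected
  tr2 <- gen_current_traces(tau_act = 0.01,
                            desens = c(A1 = 1, tau1 = 2, A2 = 1, tau2 = 2),
                            plateau = 0.1, duration = 25, sigma = 0, seed = 4)
  expect_equal(fit_desensitization(tr2$time_s, tr2$current_pA)$model, "single")
  expect_error(fit_desensitization(seq(0, 25, 0.01),
                                   seq(0, 25, 0.01) * 0 + 5),
               "fail|decay|peak")
})

test_that("model selection never over-fits noisy single decays", {
  correct <- vapply(1:50, function(i) {
    tr <- gen_current_traces(tau_act = 0.05,
                             desens = c(A1 = 1, tau1 = 2, A2 = 0, tau2 = 10),
                             plateau = 0.1, duration = 25, sample_rate = 200,
                             sigma = 0.02, seed = 4000 + i)
    fit_desensitization(tr$time_s, tr$current_pA)$model == "single"
  }, logical(1))
  expect_gte(mean(correct), 0.95)
})

test_that("weighted tau is the amplitude-weighted mean of component taus", {
  mk <- function(amp, tau) list(components = data.frame(amplitude = amp,
                                                        tau = tau))
  expect_equal(weighted_tau(mk(c(1, 1), c(2, 4))), 3.0)
  expect_equal(weighted_tau(mk(c(3, 1), c(0.5, 2))), 0.875)
  expect_equal(weighted_tau(mk(1, 1.9)), 1.9)
  # bounded by the component taus for positive amplitudes
  for (i in 1:20) {
    set.seed(i)
    a <- stats::runif(2, 0.1, 5); tt <- sort(stats::runif(2, 0.1, 10))
    w <- weighted_tau(mk(a, tt))
    expect_gte(w, tt[1]); expect_lte(w, tt[2])
  }
  expect_error(weighted_tau(mk(c(1, -1), c(1, 2))), "zero")
})

test_that("extent of desensitization at 20 s is the normalized residual current", {
  t <- seq(0, 25, by = 0.01)
  flat <- 100 * (1 - exp(-t / 0.1))
  expect_equal(extent_at_20s(t, flat), 1.0, tolerance = 1e-6)
  gone <- 100 * (1 - exp(-t / 0.1)) * exp(-t / 0.5)
  expect_equal(extent_at_20s(t, gone), 0.0, tolerance = 1e-6)
  # invariance to uniform current scaling
  tr <- gen_current_traces(tau_act = 0.134,
                           desens = c(A1 = 1, tau1 = 1.95, A2 = 0, tau2 = 10),
                           plateau = 0.1, duration = 25, sigma = 0, seed = 5)
  e1 <- extent_at_20s(tr$time_s, tr$current_pA)
  e2 <- extent_at_20s(tr$time_s, 3.7 * tr$current_pA)
  expect_equal(e1, e2)
  # closed-form oracle: I(20)/max(I) of the generating model
  i_model <- function(t) 500 * (1 - exp(-t / 0.134)) *
    (0.1 + 0.9 * exp(-t / 1.95))
  tg <- seq(0, 25, by = 1e-3)
  expect_equal(e1, i_model(20) / max(i_model(tg)), tolerance = 1e-3)
  expect_error(extent_at_20s(t[t < 20], flat[t < 20]), "domain|before")
})

test_that("dose-response fit with fixed Hill slope recovers EC50", {
  cc <- c(1, 2, 5, 10, 20, 50)
  for (ec in c(2.4, 5.1, 6.5)) {
    ii <- 800 * cc^2 / (cc^2 + ec^2)
    fit <- fit_dose_response(cc, ii)
    expect_equal(fit$ec50, ec, tolerance = 0.01)
    expect_equal(fit$i_max, 800, tolerance = 0.01)
    # current scaling scales I_max but not EC50
    fit2 <- fit_dose_response(cc, 2.5 * ii)
    expect_equal(fit2$ec50, fit$ec50, tolerance = 1e-6)
    expect_equal(fit2$i_max, 2.5 * fit$i_max, tolerance = 1e-6)
  }
  # EC50 recovery within 10% at 5% peak noise across the tested range
  set.seed(99)
  for (ec in c(2.4, 5.1, 6.5)) {
    err <- vapply(1:30, function(i) {
      ii <- 800 * cc^2 / (cc^2 + ec^2) + stats::rnorm(length(cc), 0, 40)
      abs(fit_dose_response(cc, ii)$ec50 - ec) / ec
    }, numeric(1))
    expect_lt(stats::median(err), 0.10)
  }
})

test_that("weighted taus pool across single and double fits", {
  s <- list(components = data.frame(amplitude = 1, tau = 2.0))
  d <- list(components = data.frame(amplitude = c(3, 1), tau = c(1.6, 2.8)))
  expect_equal(weighted_tau(d), 1.9)
  out <- combine_weighted_taus(list(s, d))
  expect_equal(out$mean, 1.95)
  expect_false(out$single_obs)
  # permutation symmetry
  expect_equal(combine_weighted_taus(list(d, s))$mean, out$mean)
  one <- combine_weighted_taus(list(s))
  expect_equal(one$sd, 0)
  expect_true(one$single_obs)
})

test_that("group comparisons use ANOVA/Tukey and Bonferroni designs", {
  set.seed(8)
  v <- c(rnorm(6, 0), rnorm(6, 0))
  g <- rep(c("A", "B"), each = 6)
  gc <- group_compare(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_equal(gc$anova_F, unname(tt$statistic)^2, tolerance = 1e-9)
  # identical groups: nothing significant
  v0 <- rep(c(1, 2, 3), times = 3)
  g0 <- rep(c("A", "B", "C"), each = 3)
  expect_false(any(group_compare(v0, g0)$table$significant))
  # reference design flags only the shifted group
  set.seed(9)
  v1 <- c(rnorm(6), rnorm(6) + 5, rnorm(6))
  g1 <- rep(c("WT", "M1", "M2"), each = 6)
  tab <- group_compare(v1, g1, design = "wt_vs_mutants")$table
  expect_true(tab$significant[tab$comparison == "M1 vs WT"])
  expect_false(tab$significant[tab$comparison == "M2 vs WT"])
  expect_error(group_compare(rep(1, 6), rep(c("A", "B"), 3)), "degenerate")
})

test_that("Tukey family-wise error is controlled under a simulated null", {
  set.seed(123)
  n_rep <- 500
  any_sig <- vapply(seq_len(n_rep), function(i) {
    v <- stats::rnorm(15)
    g <- rep(c("A", "B", "C"), each = 5)
    any(group_compare(v, g)$table$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.06)
})
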