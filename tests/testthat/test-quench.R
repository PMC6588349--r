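test_that("compound-fluorescence correction removes the additive offset", {
  cfg <- quench_sim_config(tau0_ms = 5, beta = 0.8, F0 = 10, Finf = 2,
                           compound_offset = 10, noise_sd = 0, seed = 3)
  ex <- gen_quench_trials(cfg)
  cfg0 <- quench_sim_config(tau0_ms = 5, beta = 0.8, F0 = 10, Finf = 2,
                            compound_offset = 0, noise_sd = 0, seed = 3)
  ex0 <- gen_quench_trials(cfg0)
  corrected <- correct_compound_fluorescence(ex$trials, ex$reference)
  expect_equal(corrected$fluorescence, ex0$trials$fluorescence, tolerance = 1e-12)

  # zero offset leaves the trace unchanged
  same <- correct_compound_fluorescence(ex0$trials, 0)
  expect_equal(same$fluorescence, ex0$trials$fluorescence)

  # corrected control trace is constant at F0
  ctrl <- corrected[corrected$trial_id == "ctrl_01", ]
  expect_true(all(abs(ctrl$fluorescence - 10) < 1e-12))

  expect_error(correct_compound_fluorescence(ex$trials, NULL), "reference")
})

test_that("stretched-exponential fit recovers noiseless parameters", {
  cfg <- quench_sim_config(tau0_ms = 5, beta = 0.8, F0 = 10, Finf = 2,
                           noise_sd = 0, seed = 1)
  tr <- gen_quench_trials(cfg)$trials
  fit <- fit_stretched_exp(tr[tr$trial_id == "tl_01", ])
  expect_equal(fit$tau0_ms, 5, tolerance = 1e-6)
  expect_equal(fit$beta, 0.8, tolerance = 1e-6)
  expect_equal(fit$F0, 10, tolerance = 1e-6)
  expect_equal(fit$Finf, 2, tolerance = 1e-6)

  # beta = 1 data: the degenerate single-exponential is fit with ~0 residual
  cfg1 <- quench_sim_config(tau0_ms = 5, beta = 1, F0 = 10, Finf = 2,
                            noise_sd = 0, seed = 1)
  tr1 <- gen_quench_trials(cfg1)$trials
  fit1 <- fit_stretched_exp(tr1[tr1$trial_id == "tl_01", ])
  expect_equal(fit1$beta, 1, tolerance = 1e-6)
  expect_lt(fit1$residual_ss, 1e-12)

  # a non-decaying trace is flagged
  flat <- data.frame(time_ms = seq(0, 150, 0.5), fluorescence = 5)
  expect_warning(ff <- fit_stretched_exp(flat), "flagged")
  expect_true(ff$flagged)
})

test_that("fit recovers tau0 and beta within 5% at 0.5% noise", {
  cfg <- quench_sim_config(tau0_ms = 5, beta = 0.8, F0 = 10, Finf = 2,
                           noise_sd = 0.005 * 10, seed = 3)
  ex <- gen_quench_trials(cfg)
  fits <- lapply(sprintf("tl_%02d", 1:9), function(id) {
    fit_stretched_exp(ex$trials[ex$trials$trial_id == id, ])
  })
  tau_hat <- mean(vapply(fits, function(f) f$tau0_ms, numeric(1)))
  beta_hat <- mean(vapply(fits, function(f) f$beta, numeric(1)))
  expect_lt(abs(tau_hat - 5) / 5, 0.05)
  expect_lt(abs(beta_hat - 0.8) / 0.8, 0.05)
})

test_that("fit equals a brute-force (tau0, beta) grid search", {
  set.seed(99)
  tt <- seq(0, 150, by = 0.5)
  for (i in 1:20) {
    tau <- runif(1, 2, 20)
    beta <- runif(1, 0.3, 1)
    y <- 2 + 8 * exp(-(tt / tau)^beta)
    fit <- fit_stretched_exp(data.frame(time_ms = tt, fluorescence = y))
    g <- oracle_stretch_grid(tt[tt >= 2 & tt <= 100], y[tt >= 2 & tt <= 100])
    # the fit must reach at least the exhaustive-search optimum, and agree
    # with the grid argmin at grid resolution (the SSE valley is curved in
    # (tau0, beta), so the discrete argmin can sit just beyond one cell)
    expect_lte(fit$residual_ss, g$sse + 1e-9)
    expect_lt(abs(log(fit$tau0_ms) - log(g$tau0)), 2 * g$dlog_tau)
    expect_lt(abs(fit$beta - g$beta), 2 * g$dbeta)
  }
})

test_that("the 2-ms quench rate follows the closed form", {
  # beta = 1 collapses to 1/tau0 at any evaluation time
  expect_equal(rate_at(list(tau0_ms = 5, beta = 1), 2), 0.2, tolerance = 1e-12)
  expect_equal(rate_at(list(tau0_ms = 5, beta = 1), 17), 0.2, tolerance = 1e-12)
  # direct evaluations of (beta/tau0) (t/tau0)^(beta-1)
  expect_equal(rate_at(list(tau0_ms = 10, beta = 0.5), 2),
               0.05 * 0.2^(-0.5), tolerance = 1e-12)
  expect_equal(round(rate_at(list(tau0_ms = 10, beta = 0.5), 2), 4), 0.1118)
  expect_equal(rate_at(list(tau0_ms = 2, beta = 0.7), 2), 0.35, tolerance = 1e-12)
  expect_error(rate_at(list(tau0_ms = -1, beta = 0.5)), "positive")
})

test_that("rate scaling identity Rate(k*tau0) = Rate(tau0) * k^(-beta) holds", {
  for (beta in c(0.3, 0.7, 1)) {
    for (k in c(0.5, 2, 10)) {
      r1 <- rate_at(list(tau0_ms = 4, beta = beta), 2)
      rk <- rate_at(list(tau0_ms = 4 * k, beta = beta), 2)
      expect_equal(rk, r1 * k^(-beta), tolerance = 1e-12)
    }
  }
})

test_that("experiment rates are averaged and control-normalized", {
  ctrl <- rate_at(list(tau0_ms = 5, beta = 1), 2)
  same <- replicate(9, list(tau0_ms = 5, beta = 1), simplify = FALSE)
  r <- experiment_rate(same, ctrl)
  expect_equal(r$normalized_rate, 1, tolerance = 1e-12)

  # simulated trials at twice the control 1/tau0, equal beta = 1
  cfg <- quench_sim_config(tau0_ms = 2.5, beta = 1, F0 = 10, Finf = 2,
                           noise_sd = 0.05, seed = 17)
  ex <- gen_quench_trials(cfg)
  fits <- lapply(sprintf("tl_%02d", 1:9), function(id) {
    fit_stretched_exp(ex$trials[ex$trials$trial_id == id, ])
  })
  r2 <- experiment_rate(fits, ctrl)
  expect_equal(r2$normalized_rate, 2, tolerance = 0.1)

  # common fluorescence rescaling leaves the normalized rate unchanged
  ex_scaled <- ex
  ex_scaled$trials$fluorescence <- 37 * ex$trials$fluorescence
  fits_s <- lapply(sprintf("tl_%02d", 1:9), function(id) {
    fit_stretched_exp(ex_scaled$trials[ex_scaled$trials$trial_id == id, ])
  })
  r3 <- experiment_rate(fits_s, ctrl)
  expect_equal(r3$normalized_rate, r2$normalized_rate, tolerance = 1e-6)

  expect_error(experiment_rate(same, 0), "positive")

  agg <- aggregate_quench_experiments(c(2, 2, 2))
  expect_equal(agg$mean, 2)
  expect_equal(agg$sem, 0)
})
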