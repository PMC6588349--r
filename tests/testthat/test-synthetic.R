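test_that("cohort generator enforces labeling and visibility rules", {
  # fully labeled pure dimers, noiseless: every trace bleaches in 2 steps
  cfg <- simpull_config(40, stoichiometry_model(1, p = 1, b = 0),
                        snr = Inf, seed = 1)
  co <- gen_photobleach_cohort(cfg)
  expect_true(all(co$truth$n_labeled == 2))
  n2 <- vapply(co$traces, function(tr) detect_steps(tr)$n_steps, numeric(1))
  bleached <- vapply(co$truth$bleach_times, function(b) all(b < 60), logical(1))
  expect_true(all(n2[bleached] == 2))

  # every emitted spot is visible and dimers carry at most 2 labels
  cfg2 <- simpull_config(5000, stoichiometry_model(0.5, p = 0.6, b = 0.1), seed = 2)
  co2 <- gen_photobleach_cohort(cfg2, emit_traces = FALSE)
  expect_true(all(co2$truth$n_labeled >= 1))
  dimers <- co2$truth$complex_type == "dimer"
  expect_true(all(co2$truth$n_labeled[dimers] <= 2))
  expect_true(all(lengths(co2$truth$bleach_times) == co2$truth$n_labeled))

  expect_error(stoichiometry_model(1.4, 0.8), "f_dimer")
  expect_error(simpull_config(0, stoichiometry_model(1, 0.8)), "n_spots")
})

test_that("label-count frequencies converge to the binomial forward model", {
  # pure dimer, p = 0.8: P(2 labels | visible) = p^2/(2p - p^2) = 2/3
  cfg <- simpull_config(50000, stoichiometry_model(1, p = 0.8, b = 0), seed = 7)
  co <- gen_photobleach_cohort(cfg, emit_traces = FALSE)
  expect_equal(mean(co$truth$n_labeled == 2), 2 / 3, tolerance = 0.015)

  # chi-square goodness of fit of the emitted categories at n = 50,000
  m <- stoichiometry_model(0.6, p = 0.8, b = 0.075)
  cfg2 <- simpull_config(50000, m, seed = 13)
  co2 <- gen_photobleach_cohort(cfg2, emit_traces = FALSE)
  cat_of <- cut(co2$truth$n_labeled, c(0, 1, 2, Inf), labels = c("1", "2", "3plus"))
  obs <- table(cat_of)
  gof <- stats::chisq.test(obs, p = forward_distribution(m))
  expect_gt(gof$p.value, 0.01)
})

test_that("generators are reproducible by seed", {
  cfg <- simpull_config(100, stoichiometry_model(0.6, 0.8, 0.05), seed = 5)
  a <- gen_photobleach_cohort(cfg)
  b <- gen_photobleach_cohort(cfg)
  expect_identical(a$truth$n_labeled, b$truth$n_labeled)
  expect_identical(a$traces[[17]]$intensity, b$traces[[17]]$intensity)

  # different seeds: statistically indistinguishable category frequencies
  big1 <- gen_photobleach_cohort(
    simpull_config(20000, stoichiometry_model(0.6, 0.8, 0), seed = 1),
    emit_traces = FALSE)
  big2 <- gen_photobleach_cohort(
    simpull_config(20000, stoichiometry_model(0.6, 0.8, 0), seed = 2),
    emit_traces = FALSE)
  tab <- rbind(table(factor(pmin(big1$truth$n_labeled, 3), levels = 1:3)),
               table(factor(pmin(big2$truth$n_labeled, 3), levels = 1:3)))
  expect_gt(stats::chisq.test(tab[, colSums(tab) > 0])$p.value, 0.01)
})

test_that("FRET generator conserves total intensity and records ground truth", {
  prot <- make_protocol(delta = 0.10, tau_on = 5, tau_off = 5, epoch_len = 60)
  sim <- gen_fret_series(prot)
  # noiseless: donor + acceptor = total at every sample
  expect_equal(sim$series$donor + sim$series$acceptor,
               rep(1000, length(sim$series$time_s)), tolerance = 1e-12)
  # plateau FRET approaches baseline + delta = 0.40
  expect_equal(sim$truth$delta_fret_true, 0.10)
  expect_equal(max(sim$series$fret_true), 0.40, tolerance = 1e-4)
  # closed-form 10-90% times recorded as ground truth
  prot2 <- make_protocol(delta = 0.10, tau_on = 6.51, tau_off = 2)
  expect_equal(gen_fret_series(prot2)$truth$t10_90_on_s, 6.51 * log(9),
               tolerance = 1e-12)
  expect_equal(round(gen_fret_series(prot2)$truth$t10_90_on_s, 1), 14.3)

  # epoch beyond the series end is rejected
  ep <- data.frame(label = "late", start_s = 100, end_s = 220,
                   drug = "d", concentration_uM = 1)
  kin <- data.frame(drug = "d", tau_on_s = 1, tau_off_s = 1, max_delta_fret = 0.1)
  expect_error(fret_protocol(ep, kin, duration_s = 150), "beyond")
  # FRET must stay inside [0, 1]
  kin$max_delta_fret <- 0.9
  expect_error(fret_protocol(ep, kin), "\\[0, 1\\]")
})

test_that("dose-response generator evaluates the Hill equation exactly", {
  d <- gen_dose_response(ec50_uM = 1.2, hill_n = 1, emax = 1,
                         concentrations_uM = c(0, 1.2, 120), noise_sd = 0)
  expect_equal(d$response[d$concentration_uM == 0], 0)
  expect_equal(d$response[d$concentration_uM == 1.2], 0.5, tolerance = 1e-12)

  ly48 <- dose_response_preset("LY48-TMD")
  expect_equal(ly48$ec50_uM, 1.2)
  d2 <- gen_dose_response(ly48$ec50_uM, ly48$hill_n, ly48$emax,
                          concentrations_uM = 1.2, noise_sd = 0)
  expect_equal(d2$response, ly48$emax / 2, tolerance = 1e-12)

  expect_error(gen_dose_response(1, 1, 1, numeric(0)), "empty")
  expect_error(dose_response_preset("nope"), "unknown preset")
})

test_that("current-trace generator is a deterministic exponential responder", {
  ep <- data.frame(start_s = 10, end_s = 90)
  tr <- gen_current_trace(6.51, 6.51, plateau = 1, epochs = ep,
                          sample_rate_hz = 20, noise_sd = 0)
  k <- time_10_90(tr, epoch_start_s = 10, direction = "on", epoch_end_s = 90)
  expect_equal(k$t_10_90_s, 6.51 * log(9), tolerance = 0.05)

  flat <- gen_current_trace(1, 1, plateau = 0, epochs = ep, noise_sd = 0)
  expect_true(all(flat$intensity == 0))
  expect_error(gen_current_trace(-1, 1, 1, ep), "positive")
})

test_that("quench generator inverts the stretched-exponential model", {
  cfg <- quench_sim_config(tau0_ms = 5, beta = 1, F0 = 10, Finf = 2,
                           compound_offset = 3, noise_sd = 0, seed = 1)
  ex <- gen_quench_trials(cfg)
  expect_equal(sum(ex$trials$quencher), 9 * length(unique(ex$trials$time_ms)))
  q1 <- ex$trials[ex$trials$trial_id == "tl_01", ]
  # beta = 1 degenerates to a single exponential
  expect_equal(q1$fluorescence,
               2 + 8 * exp(-q1$time_ms / 5) + 3, tolerance = 1e-12)
  # t -> infinity: F -> Finf + offset
  expect_equal(q1$fluorescence[nrow(q1)], 2 + 3, tolerance = 1e-6)
  # controls are flat at F0 + offset
  c1 <- ex$trials[ex$trials$trial_id == "ctrl_01", ]
  expect_true(all(c1$fluorescence == 13))

  expect_error(quench_sim_config(beta = 1.2), "beta")
  expect_error(quench_sim_config(F0 = 1, Finf = 2), "F0 > Finf")
})
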