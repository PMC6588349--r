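test_that("noise estimation is robust to steps and consistent for Gaussians", {
  tt <- seq(0, 99.9, by = 0.1)
  expect_equal(estimate_noise(intensity_trace("c", tt[1:100], rep(3, 100))), 0)

  set.seed(101)
  tr <- intensity_trace("g", seq_len(1e5) * 0.05, rnorm(1e5, 0, 1))
  expect_equal(estimate_noise(tr), 1, tolerance = 0.02)

  # a noiseless 2-step staircase: the two step differences are sparse
  # outliers among thousands of zero differences
  x <- c(rep(2, 1500), rep(1, 1500), rep(0, 1500))
  tr2 <- intensity_trace("s", seq_along(x) * 0.05, x)
  expect_lt(estimate_noise(tr2), 1e-12)
})

test_that("steps in a noiseless staircase are found exactly", {
  tt <- seq(0, 9.95, by = 0.05)
  x <- c(rep(2, 60), rep(1, 80), rep(0, 60))  # steps at t = 3 s and 7 s
  fit <- detect_steps(intensity_trace("a", tt, x))
  expect_equal(fit$n_steps, 2L)
  expect_equal(fit$step_times_s, c(3, 7), tolerance = 1e-12)
  expect_equal(fit$levels, c(2, 1, 0), tolerance = 1e-12)
  expect_equal(classify_spot(fit), "2")

  flat <- detect_steps(intensity_trace("z", tt, rep(0, length(tt))))
  expect_equal(flat$n_steps, 0L)
  expect_equal(classify_spot(flat), "rejected")
})

test_that("detection equals the exhaustive-search oracle on noiseless traces", {
  cases <- list(
    random_staircase(60, 1, seed = 1),
    random_staircase(120, 2, seed = 2),
    random_staircase(200, 3, seed = 3),
    random_staircase(90, 0, seed = 4),
    random_staircase(150, 2, seed = 5),
    random_staircase(200, 1, seed = 6)
  )
  for (cs in cases) {
    fit <- detect_steps(cs$trace, max_steps = 3)
    oracle <- oracle_exhaustive_steps(cs$x, max_k = 3)
    expect_equal(fit$n_steps, oracle$k)
    expect_equal(which(cs$trace$time_s %in% fit$step_times_s) - 1L,
                 as.integer(oracle$bounds))
  }
})

test_that("detection recovers true step counts on a simulated cohort", {
  cfg <- simpull_config(1000, stoichiometry_model(0.6, p = 0.8, b = 0),
                        bleach_tau_s = 10, frame_rate_hz = 20,
                        movie_length_s = 60, snr = 5, seed = 11)
  co <- gen_photobleach_cohort(cfg)
  fits <- lapply(co$traces, detect_steps)
  cats <- vapply(fits, classify_spot, character(1))
  truth_cat <- as.character(pmin(co$truth$n_labeled, 3))
  got <- ifelse(cats == "3plus", "3", cats)
  # restrict to spots whose true steps are >= 20 frames (1 s) apart and
  # that fully bleach within the movie
  sep <- vapply(seq_len(nrow(co$truth)), function(i) {
    bt <- sort(co$truth$bleach_times[[i]])
    all(bt < cfg$movie_length_s - 2) && all(diff(c(0, bt)) >= 1)
  }, logical(1))
  expect_gte(mean(got[sep] == truth_cat[sep]), 0.95)
})

test_that("detection is invariant to affine intensity rescaling", {
  set.seed(12)
  tt <- seq(0, 59.95, by = 0.05)
  x <- c(rep(2, 300), rep(1, 500), rep(0, 400)) + rnorm(1200, 0, 0.2)
  base <- detect_steps(intensity_trace("b", tt, x))
  for (g in c(0.5, 3, 100)) {
    for (off in c(-5, 0, 12)) {
      fit <- detect_steps(intensity_trace("b2", tt, g * x + off))
      expect_equal(fit$n_steps, base$n_steps,
                   info = sprintf("gain %g offset %g", g, off))
    }
  }
})

test_that("spot classification applies the full-bleach and step-height rules", {
  mk <- function(n_steps, levels, sigma) {
    structure(list(trace_id = "t", n_steps = n_steps,
                   step_times_s = seq_len(n_steps), levels = levels,
                   sse = 0, noise_sd_hat = sigma), class = "step_fit")
  }
  expect_equal(classify_spot(mk(2L, c(2, 1, 0), 0.1)), "2")
  expect_equal(classify_spot(mk(5L, c(5, 4, 3, 2, 1, 0), 0.1)), "3plus")
  expect_equal(classify_spot(mk(0L, 1, 0.1)), "rejected")
  # did not bleach to zero
  expect_equal(classify_spot(mk(1L, c(2, 1), 0.1)), "rejected")
  # a fitted step smaller than 3 sigma
  expect_equal(classify_spot(mk(2L, c(2, 1.8, 0), 0.1)), "rejected")
})

test_that("movie summaries and condition aggregates follow the conventions", {
  s <- summarize_movie(c(rep("1", 40), rep("2", 60)), "m1")
  expect_equal(s$pct_two_step, 60)
  expect_equal(summarize_movie(rep("1", 100))$pct_two_step, 0)
  expect_equal(summarize_movie(c(rep("1", 55), rep("2", 45)))$pct_two_step, 45)
  # percentage is computed among accepted spots only
  s2 <- summarize_movie(c(rep("1", 40), rep("2", 60), rep("rejected", 50)))
  expect_equal(s2$pct_two_step, 60)
  expect_equal(s2$n_accepted, 100)
  expect_error(summarize_movie(rep("rejected", 5), "bad"), "bad")
  # order invariance
  set.seed(3)
  cc <- sample(c(rep("1", 30), rep("2", 20), rep("3plus", 5)))
  expect_equal(summarize_movie(cc)$pct_two_step,
               summarize_movie(rev(cc))$pct_two_step)

  mk <- function(p1, p2) summarize_movie(c(rep("1", p1), rep("2", p2)))
  agg <- aggregate_condition(list(mk(55, 45), mk(55, 45), mk(55, 45)))
  expect_equal(agg$mean_pct_two_step, 45)
  expect_equal(agg$sem, 0)
  agg2 <- aggregate_condition(list(mk(60, 40), mk(50, 50)))
  expect_equal(agg2$mean_pct_two_step, 45)
  expect_equal(agg2$sem, 5)   # sd({40,50})/sqrt(2) = 5
  expect_warning(a1 <- aggregate_condition(list(mk(60, 40))), "undefined")
  expect_false(a1$sem_defined)
})

test_that("twenty simulated movies reproduce the expected two-step percentage", {
  # forward-model expectation at f = 0.6, p = 0.8:
  # theta2 = f p^2 / (f (2p - p^2) + (1 - f) p) = 42.9% among accepted spots
  expected <- 100 * forward_distribution(stoichiometry_model(0.6, 0.8, 0))[["2"]]
  movies <- lapply(1:20, function(m) {
    cfg <- simpull_config(250, stoichiometry_model(0.6, p = 0.8, b = 0),
                          snr = 5, seed = 500 + m)
    co <- gen_photobleach_cohort(cfg)
    cats <- vapply(co$traces, function(tr) classify_spot(detect_steps(tr)),
                   character(1))
    summarize_movie(cats, paste0("m", m))
  })
  agg <- aggregate_condition(movies)
  expect_lt(abs(agg$mean_pct_two_step - expected), 2)
})
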