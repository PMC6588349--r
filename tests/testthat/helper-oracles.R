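# Independent oracles used to validate the package's own algorithms.
# These deliberately use brute force / closed forms, never the package code.

# exhaustive least-squares segmentation: tries every change-point set with
# k = 0..max_k steps and returns the smallest k attaining the minimal SSE
oracle_exhaustive_steps <- function(x, max_k = 3L) {
  n <- length(x)
  sse_of <- function(bounds) {
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    sum(vapply(seq_along(starts), function(i) {
      seg <- x[starts[i]:ends[i]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  best <- list(k = 0L, bounds = integer(0), sse = sse_of(integer(0)))
  for (k in seq_len(max_k)) {
    combs <- utils::combn(n - 1L, k)
    for (j in seq_len(ncol(combs))) {
      s <- sse_of(combs[, j])
      if (s < best$sse - 1e-9 * max(best$sse, 1)) {
        best <- list(k = k, bounds = combs[, j], sse = s)
      }
    }
  }
  best
}

# random noiseless descending staircase trace for oracle comparisons
random_staircase <- function(n, k, seed) {
  set.seed(seed)
  bounds <- sort(sample(seq(5L, n - 5L), k))
  levels <- sort(stats::runif(k + 1L, 0, 5), decreasing = TRUE)
  lens <- diff(c(0L, bounds, n))
  x <- rep(levels, lens)
  list(x = x, bounds = bounds, levels = levels,
       trace = intensity_trace(paste0("stair", seed), seq_len(n) * 0.05, x))
}

# brute-force multinomial likelihood grid over the dimer fraction
oracle_ml_grid <- function(counts, p, b, grid = seq(0, 1, by = 1e-4)) {
  vis_dimer <- 2 * p - p^2
  ll <- vapply(grid, function(f) {
    theta_vis <- f * vis_dimer + (1 - f) * p
    p2b <- (f * vis_dimer / theta_vis) * p^2 / vis_dimer
    pr <- c((1 - b) * (1 - p2b), (1 - b) * p2b + b * (1 - p2b), b * p2b)
    keep <- counts > 0
    if (any(keep & pr <= 0)) return(-Inf)
    sum(counts[keep] * log(pr[keep]))
  }, numeric(1))
  grid[which.max(ll)]
}

# brute-force (tau0, beta) grid search for the stretched exponential; the
# two linear parameters (Finf, amplitude) are solved exactly at each node,
# profiling the same surface the nonlinear fit explores
oracle_stretch_grid <- function(tt, y,
                                tau_grid = exp(seq(log(0.5), log(25),
                                                   length.out = 100)),
                                beta_grid = seq(0.05, 1, length.out = 100)) {
  best <- c(NA, NA); best_sse <- Inf
  for (b in beta_grid) {
    for (tau in tau_grid) {
      basis <- exp(-(tt / tau)^b)
      s <- sum(stats::.lm.fit(cbind(1, basis), y)$residuals^2)
      if (s < best_sse) { best_sse <- s; best <- c(tau, b) }
    }
  }
  list(tau0 = best[1], beta = best[2], sse = best_sse,
       dlog_tau = diff(log(tau_grid[1:2])), dbeta = diff(beta_grid[1:2]))
}

# single-epoch protocol helper used across FRET tests
make_protocol <- function(delta, tau_on = 2, tau_off = 2, baseline = 0.30,
                          epoch_len = 60, noise_sd = 0, rate = 5, seed = 0,
                          drug = "drugA") {
  ep <- data.frame(label = "ep1", start_s = 30, end_s = 30 + epoch_len,
                   drug = drug, concentration_uM = 10)
  kin <- data.frame(drug = drug, tau_on_s = tau_on, tau_off_s = tau_off,
                    max_delta_fret = delta)
  fret_protocol(ep, kin, baseline_fret = baseline, total_intensity = 1000,
                noise_sd = noise_sd, sample_rate_hz = rate,
                duration_s = 30 + epoch_len + 40, seed = seed)
}
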