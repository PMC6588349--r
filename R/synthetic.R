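#' Configuration for a simulated single-molecule pulldown cohort
#'
#' Defaults reflect the imaging conditions the pipeline is built for:
#' 20 Hz sCMOS acquisition, per-fluorophore exponential bleaching with a
#' 10 s time constant, and a signal-to-noise ratio of 5 (unit step height
#' over Gaussian read-noise s.d.).
#'
#' @param n_spots number of visible spots to emit.
#' @param model a [stoichiometry_model()] giving the monomer/dimer mix,
#'   labeling efficiency and chance-colocalization background.
#' @param bleach_tau_s mean exponential bleaching time per fluorophore (s).
#' @param frame_rate_hz acquisition rate (default 20).
#' @param movie_length_s movie duration (s).
#' @param snr unit step height divided by noise s.d.; `Inf` gives noiseless
#'   traces.
#' @param unit_intensity fluorescence units contributed by one fluorophore.
#' @param seed integer RNG seed.
#' @return object of class `simpull_config`.
#' @export
simpull_config <- function(n_spots, model, bleach_tau_s = 10, frame_rate_hz = 20,
                           movie_length_s = 60, snr = 5, unit_intensity = 1,
                           seed = 0L) {
  stopifnot(inherits(model, "stoichiometry_model"))
  if (n_spots <= 0) stop("invalid SimPullConfig: n_spots must be positive")
  if (bleach_tau_s <= 0) stop("invalid SimPullConfig: bleach_tau_s must be positive")
  if (snr <= 0) stop("invalid SimPullConfig: snr must be positive")
  if (frame_rate_hz <= 0) stop("invalid SimPullConfig: frame_rate_hz must be positive")
  if (movie_length_s <= 0) stop("invalid SimPullConfig: movie_length_s must be positive")
  structure(
    list(n_spots = as.integer(n_spots), model = model, bleach_tau_s = bleach_tau_s,
         frame_rate_hz = frame_rate_hz, movie_length_s = movie_length_s,
         snr = snr, unit_intensity = unit_intensity, seed = as.integer(seed)),
    class = "simpull_config"
  )
}

# sample per-spot ground truth (complex type, label counts, bleach times) by
# rejection: complexes with zero labels are invisible and never emitted
.sample_spot_truth <- function(config) {
  m <- config$model
  n <- config$n_spots
  p <- m$p
  if (p <= 0) stop("labeling efficiency p must be > 0 to emit visible spots")
  theta_vis <- m$f_dimer * (2 * p - p^2) + m$f_monomer * p
  is_dimer <- logical(0)
  n_lab <- integer(0)
  while (length(n_lab) < n) {
    todo <- n - length(n_lab)
    batch <- max(ceiling(1.5 * todo / theta_vis), 100L)
    d <- stats::runif(batch) < m$f_dimer
    lab <- stats::rbinom(batch, ifelse(d, 2L, 1L), p)
    keep <- lab > 0L
    is_dimer <- c(is_dimer, d[keep])
    n_lab <- c(n_lab, lab[keep])
  }
  is_dimer <- is_dimer[seq_len(n)]
  n_lab <- n_lab[seq_len(n)]
  extra <- stats::runif(n) < m$b          # one extra labeled monomer
  n_labeled <- n_lab + as.integer(extra)
  complex_type <- ifelse(extra, "colocalized_pair",
                         ifelse(is_dimer, "dimer", "monomer"))
  bleach_times <- lapply(n_labeled, function(k) stats::rexp(k, rate = 1 / config$bleach_tau_s))
  data.frame(
    spot_id = sprintf("spot_%05d", seq_len(n)),
    complex_type = complex_type,
    n_labeled = n_labeled,
    unit_intensity = config$unit_intensity,
    bleach_times = I(bleach_times),
    stringsAsFactors = FALSE
  )
}

#' Simulate a photobleaching cohort with known ground truth
#'
#' Draws complex types from the stoichiometry model, labels each subunit
#' independently with probability `p`, discards invisible (unlabeled)
#' complexes, attaches one extra labeled monomer with probability `b`
#' (chance colocalization), and renders each spot as a staircase trace:
#' `intensity(t) = unit_intensity * (number of unbleached fluorophores at t)`
#' plus Gaussian read noise of s.d. `unit_intensity / snr`. Bleach times are
#' i.i.d. exponential with mean `bleach_tau_s`.
#'
#' @param config a [simpull_config()].
#' @param emit_traces render intensity traces (set FALSE to sample ground
#'   truth only, e.g. for large-n distributional checks).
#' @return list of class `simpull_cohort` with `traces` (list of
#'   [intensity_trace()], or NULL) and `truth` (data.frame with spot_id,
#'   complex_type, n_labeled, unit_intensity and a list-column of
#'   bleach_times).
#' @export
gen_photobleach_cohort <- function(config, emit_traces = TRUE) {
  stopifnot(inherits(config, "simpull_config"))
  set.seed(config$seed)
  truth <- .sample_spot_truth(config)
  traces <- NULL
  if (emit_traces) {
    n_t <- floor(config$movie_length_s * config$frame_rate_hz)
    tt <- (seq_len(n_t) - 1L) / config$frame_rate_hz
    noise_sd <- if (is.finite(config$snr)) config$unit_intensity / config$snr else 0
    traces <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      bt <- truth$bleach_times[[i]]
      alive <- rep(0, n_t)
      for (b in bt) alive <- alive + (tt < b)
      y <- config$unit_intensity * alive
      if (noise_sd > 0) y <- y + stats::rnorm(n_t, 0, noise_sd)
      traces[[i]] <- intensity_trace(truth$spot_id[i], tt, y, channel = "bleach")
    }
    names(traces) <- truth$spot_id
  }
  structure(list(traces = traces, truth = truth, config = config),
            class = "simpull_cohort")
}

#' Drug-application protocol for a simulated FRET recording
#'
#' @param epochs data.frame with columns label, start_s, end_s, drug,
#'   concentration_uM; epochs must be time-ordered and non-overlapping.
#' @param kinetics data.frame with columns drug, tau_on_s, tau_off_s,
#'   max_delta_fret (one row per drug used in `epochs`).
#' @param baseline_fret basal FRET ratio in \[0, 1\].
#' @param total_intensity donor + acceptor expectation (constant over time).
#' @param noise_sd Gaussian noise s.d. added independently per channel.
#' @param sample_rate_hz sampling rate (default 1, matching slow imaging).
#' @param duration_s total recording length.
#' @param seed integer RNG seed.
#' @return object of class `fret_protocol`.
#' @export
fret_protocol <- function(epochs, kinetics, baseline_fret = 0.3,
                          total_intensity = 1000, noise_sd = 0,
                          sample_rate_hz = 1, duration_s = NULL, seed = 0L) {
  need <- c("label", "start_s", "end_s", "drug", "concentration_uM")
  if (!all(need %in% names(epochs))) {
    stop("epochs must have columns ", paste(need, collapse = ", "))
  }
  needk <- c("drug", "tau_on_s", "tau_off_s", "max_delta_fret")
  if (!all(needk %in% names(kinetics))) {
    stop("kinetics must have columns ", paste(needk, collapse = ", "))
  }
  epochs <- epochs[order(epochs$start_s), , drop = FALSE]
  if (any(epochs$end_s <= epochs$start_s)) stop("each epoch must end after it starts")
  if (nrow(epochs) > 1 && any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
    stop("epochs must be non-overlapping and time-ordered")
  }
  if (is.null(duration_s)) duration_s <- max(epochs$end_s) + 60
  if (max(epochs$end_s) > duration_s) stop("epoch extends beyond the end of the series")
  miss <- setdiff(epochs$drug, kinetics$drug)
  if (length(miss)) stop("no kinetics given for drug(s): ", paste(miss, collapse = ", "))
  if (baseline_fret < 0 || baseline_fret > 1) stop("baseline_fret must be in [0, 1]")
  hi <- baseline_fret + kinetics$max_delta_fret
  if (any(hi < 0 | hi > 1)) stop("baseline_fret + max_delta_fret must stay in [0, 1]")
  structure(
    list(epochs = epochs, kinetics = kinetics, baseline_fret = baseline_fret,
         total_intensity = total_intensity, noise_sd = noise_sd,
         sample_rate_hz = sample_rate_hz, duration_s = duration_s,
         seed = as.integer(seed)),
    class = "fret_protocol"
  )
}

#' Simulate a two-channel FRET recording with drug epochs
#'
#' The true FRET ratio relaxes single-exponentially toward
#' `baseline_fret + max_delta_fret` during each drug epoch (time constant
#' `tau_on_s`) and back toward baseline afterwards (`tau_off_s`). Channels
#' are anti-correlated by construction: `acceptor = total * FRET` and
#' `donor = total * (1 - FRET)`, each plus independent Gaussian noise.
#'
#' @param protocol a [fret_protocol()].
#' @return list of class `fret_sim` with `series` (a `fret_series`: time_s,
#'   donor, acceptor, epochs and the noiseless `fret_true`) and `truth`
#'   (per-epoch data.frame: label, drug, delta_fret_true — the asymptotic
#'   plateau change, fret_at_end — the value actually reached, t10_90_on_s
#'   and t10_90_off_s — the closed-form `tau * log(9)` transition times).
#' @export
gen_fret_series <- function(protocol) {
  stopifnot(inherits(protocol, "fret_protocol"))
  set.seed(protocol$seed)
  dt <- 1 / protocol$sample_rate_hz
  tt <- seq(0, protocol$duration_s, by = dt)
  kin <- protocol$kinetics
  ep <- protocol$epochs
  fret_true <- numeric(length(tt))
  v <- protocol$baseline_fret
  last_off_tau <- kin$tau_off_s[1]
  for (i in seq_along(tt)) {
    inside <- which(ep$start_s <= tt[i] & tt[i] < ep$end_s)
    if (length(inside)) {
      krow <- kin[kin$drug == ep$drug[inside[1]], ]
      target <- protocol$baseline_fret + krow$max_delta_fret
      tau <- krow$tau_on_s
      last_off_tau <- krow$tau_off_s
    } else {
      target <- protocol$baseline_fret
      tau <- last_off_tau
    }
    if (i > 1) v <- target + (v - target) * exp(-dt / tau)
    fret_true[i] <- v
  }
  total <- protocol$total_intensity
  acceptor <- total * fret_true
  donor <- total * (1 - fret_true)
  if (protocol$noise_sd > 0) {
    acceptor <- acceptor + stats::rnorm(length(tt), 0, protocol$noise_sd)
    donor <- donor + stats::rnorm(length(tt), 0, protocol$noise_sd)
  }
  series <- structure(
    list(time_s = tt, donor = donor, acceptor = acceptor,
         epochs = ep, fret_true = fret_true),
    class = "fret_series"
  )
  kidx <- match(ep$drug, kin$drug)
  truth <- data.frame(
    label = ep$label, drug = ep$drug,
    delta_fret_true = kin$max_delta_fret[kidx],
    fret_at_end = fret_true[vapply(ep$end_s, function(e) max(which(tt < e)), integer(1))],
    t10_90_on_s = kin$tau_on_s[kidx] * log(9),
    t10_90_off_s = kin$tau_off_s[kidx] * log(9),
    stringsAsFactors = FALSE
  )
  structure(list(series = series, truth = truth), class = "fret_sim")
}

# fitted dose-response parameters reported for this receptor system;
# Hill slopes were not printed and default to 1, efficacies are on the
# normalization scale of the corresponding assay
.dose_presets <- list(
  "LY48-GIRK"      = list(ec50_uM = 0.23, hill_n = 1, emax = 0.70),
  "LY48-GIRK-R57A" = list(ec50_uM = 0.29, hill_n = 1, emax = 0.70),
  "LY48-TMD"       = list(ec50_uM = 1.2,  hill_n = 1, emax = 1.00),
  "TASP-TMD"       = list(ec50_uM = 0.9,  hill_n = 1, emax = 1.30),
  "CBiPES-TMD"     = list(ec50_uM = 3.5,  hill_n = 1, emax = 1.00),
  "BINA-TMD"       = list(ec50_uM = 3.1,  hill_n = 1, emax = 1.00),
  "Ro64-TMD"       = list(ec50_uM = 2.1,  hill_n = 1, emax = 1.00)
)

#' Preset Hill parameters for the drugs characterized in this system
#'
#' @param name one of `names(smpharm:::.dose_presets)`, e.g. `"LY48-GIRK"`
#'   (GIRK activation, EC50 0.23 uM, efficacy 0.70 of saturating glutamate),
#'   `"LY48-TMD"` (inter-TMD FRET, EC50 1.2 uM), `"TASP-TMD"` (EC50 0.9 uM,
#'   efficacy 1.3x LY48), `"Ro64-TMD"` (EC50 2.1 uM).
#' @return list with `ec50_uM`, `hill_n`, `emax`.
#' @export
dose_response_preset <- function(name) {
  if (!name %in% names(.dose_presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(.dose_presets), collapse = ", "))
  }
  .dose_presets[[name]]
}

#' Simulate a dose-response table from a Hill model
#'
#' `response = emax * c^n / (c^n + EC50^n) + noise`, per replicate.
#'
#' @param ec50_uM half-maximal concentration (uM), > 0.
#' @param hill_n Hill coefficient, > 0.
#' @param emax maximal response.
#' @param concentrations_uM non-negative concentrations (uM).
#' @param noise_sd Gaussian noise s.d. per replicate measurement.
#' @param n_replicates replicates per concentration.
#' @param seed integer RNG seed.
#' @return data.frame with columns concentration_uM, response, replicate.
#' @export
gen_dose_response <- function(ec50_uM, hill_n = 1, emax = 1, concentrations_uM,
                              noise_sd = 0, n_replicates = 1, seed = 0L) {
  if (ec50_uM <= 0) stop("ec50_uM must be positive")
  if (!length(concentrations_uM)) stop("concentration list must not be empty")
  if (any(concentrations_uM < 0)) stop("concentrations must be non-negative")
  set.seed(as.integer(seed))
  df <- expand.grid(replicate = seq_len(n_replicates),
                    concentration_uM = concentrations_uM)
  mu <- emax * df$concentration_uM^hill_n /
    (df$concentration_uM^hill_n + ec50_uM^hill_n)
  df$response <- mu + if (noise_sd > 0) stats::rnorm(nrow(df), 0, noise_sd) else 0
  df[, c("concentration_uM", "response", "replicate")]
}

#' Simulate a drug-evoked current (or FRET-like) trace
#'
#' Single-exponential approach to `plateau` during each application epoch
#' (time constant `tau_on_s`) and single-exponential return to zero after
#' (`tau_off_s`). Deterministic when `noise_sd = 0`.
#'
#' @param tau_on_s,tau_off_s activation/deactivation time constants (s), > 0.
#' @param plateau steady-state response amplitude.
#' @param epochs data.frame with columns start_s, end_s (drug application).
#' @param sample_rate_hz sampling rate.
#' @param duration_s trace length (default: last epoch end + 5 off taus).
#' @param noise_sd Gaussian noise s.d.
#' @param seed integer RNG seed.
#' @return an [intensity_trace()] with channel `"current"`.
#' @export
gen_current_trace <- function(tau_on_s, tau_off_s, plateau, epochs,
                              sample_rate_hz = 20, duration_s = NULL,
                              noise_sd = 0, seed = 0L) {
  if (tau_on_s <= 0 || tau_off_s <= 0) stop("time constants must be positive")
  if (!all(c("start_s", "end_s") %in% names(epochs))) {
    stop("epochs must have columns start_s, end_s")
  }
  if (is.null(duration_s)) duration_s <- max(epochs$end_s) + 5 * tau_off_s
  set.seed(as.integer(seed))
  dt <- 1 / sample_rate_hz
  tt <- seq(0, duration_s, by = dt)
  y <- numeric(length(tt))
  v <- 0
  for (i in seq_along(tt)) {
    inside <- any(epochs$start_s <= tt[i] & tt[i] < epochs$end_s)
    target <- if (inside) plateau else 0
    tau <- if (inside) tau_on_s else tau_off_s
    if (i > 1) v <- target + (v - target) * exp(-dt / tau)
    y[i] <- v
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(tt), 0, noise_sd)
  intensity_trace("current_1", tt, y, channel = "current")
}

#' Configuration for simulated stopped-flow thallium quench trials
#'
#' Defaults follow the stopped-flow protocol the analysis targets: nine
#' successive trials with the quencher and four without, a < 2 ms
#' instrument dead time (the fit window starts at 2 ms), and a stretched
#' exponential decay reflecting the dispersity of the vesicle population.
#'
#' @param tau0_ms stretched-exponential time parameter (ms), > 0.
#' @param beta stretching exponent in (0, 1\]; 1 is a homogeneous sample.
#' @param F0,Finf initial and asymptotic fluorescence, `F0 > Finf >= 0`.
#' @param compound_offset additive fluorescence of the modulator compound.
#' @param n_quench_trials trials with Tl+ (default 9).
#' @param n_control_trials trials without Tl+ (default 4).
#' @param dt_ms sampling interval (ms).
#' @param t_max_ms trial duration (ms).
#' @param noise_sd Gaussian noise s.d.
#' @param seed integer RNG seed.
#' @return object of class `quench_sim_config`.
#' @export
quench_sim_config <- function(tau0_ms = 5, beta = 0.8, F0 = 10, Finf = 2,
                              compound_offset = 0, n_quench_trials = 9,
                              n_control_trials = 4, dt_ms = 0.5, t_max_ms = 150,
                              noise_sd = 0, seed = 0L) {
  if (beta <= 0 || beta > 1) stop("invalid QuenchSimConfig: beta must be in (0, 1]")
  if (!(F0 > Finf) || Finf < 0) stop("invalid QuenchSimConfig: need F0 > Finf >= 0")
  if (tau0_ms <= 0) stop("invalid QuenchSimConfig: tau0_ms must be positive")
  structure(
    list(tau0_ms = tau0_ms, beta = beta, F0 = F0, Finf = Finf,
         compound_offset = compound_offset,
         n_quench_trials = as.integer(n_quench_trials),
         n_control_trials = as.integer(n_control_trials),
         dt_ms = dt_ms, t_max_ms = t_max_ms, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "quench_sim_config"
  )
}

#' Simulate stopped-flow quench trials
#'
#' Quencher trials follow
#' `F(t) = Finf + (F0 - Finf) * exp(-(t / tau0)^beta) + compound_offset`
#' plus noise; control (no-quencher) trials are constant at
#' `F0 + compound_offset` plus noise. A compound-only reference trace at
#' the bare `compound_offset` level is emitted for the additive
#' compound-fluorescence correction.
#'
#' @param config a [quench_sim_config()].
#' @return list of class `quench_experiment` with `trials` (data.frame:
#'   time_ms, fluorescence, trial_id, quencher), `reference` (data.frame:
#'   time_ms, fluorescence — compound-only), and `config`.
#' @export
gen_quench_trials <- function(config) {
  stopifnot(inherits(config, "quench_sim_config"))
  set.seed(config$seed)
  tt <- seq(0, config$t_max_ms, by = config$dt_ms)
  decay <- config$Finf + (config$F0 - config$Finf) * exp(-(tt / config$tau0_ms)^config$beta)
  one_trial <- function(id, quencher) {
    mu <- if (quencher) decay else rep(config$F0, length(tt))
    y <- mu + config$compound_offset
    if (config$noise_sd > 0) y <- y + stats::rnorm(length(tt), 0, config$noise_sd)
    data.frame(time_ms = tt, fluorescence = y, trial_id = id, quencher = quencher)
  }
  trials <- do.call(rbind, c(
    lapply(seq_len(config$n_quench_trials), function(i) one_trial(sprintf("tl_%02d", i), TRUE)),
    lapply(seq_len(config$n_control_trials), function(i) one_trial(sprintf("ctrl_%02d", i), FALSE))
  ))
  ref <- data.frame(
    time_ms = tt,
    fluorescence = config$compound_offset +
      if (config$noise_sd > 0) stats::rnorm(length(tt), 0, config$noise_sd) else 0
  )
  structure(list(trials = trials, reference = ref, config = config),
            class = "quench_experiment")
}
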