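#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `r(c) = emax * c^n / (c^n + EC50^n)` (baseline fixed
#' at 0 by default; set `free_baseline = TRUE` to add an additive baseline).
#' Initialization: EC50 at the tested concentration whose mean response is
#' nearest half-max, Hill slope 1. Parameter standard errors come from the
#' curvature at the optimum. Replicates are fitted unweighted.
#'
#' @param concentrations_uM concentrations (uM), >= 4 distinct values.
#' @param responses responses, same length.
#' @param free_baseline fit an additive baseline (default FALSE).
#' @return object of class `hill_fit`: `ec50_uM`, `hill_n`, `emax`,
#'   `baseline`, `se` (named vector), `residual_ss`, `extrapolated` (EC50
#'   outside the tested range), `unidentifiable` (flat data or failed fit).
#' @export
fit_hill <- function(concentrations_uM, responses, free_baseline = FALSE) {
  if (length(concentrations_uM) != length(responses)) {
    stop("concentrations and responses must have the same length")
  }
  if (length(unique(concentrations_uM)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  if (any(concentrations_uM < 0)) stop("concentrations must be non-negative")
  conc <- concentrations_uM
  resp <- responses
  out <- list(ec50_uM = NA_real_, hill_n = NA_real_, emax = NA_real_,
              baseline = 0, se = c(emax = NA_real_, ec50_uM = NA_real_, hill_n = NA_real_),
              residual_ss = NA_real_, extrapolated = FALSE, unidentifiable = FALSE)
  class(out) <- "hill_fit"

  spread <- diff(range(resp))
  if (spread <= 1e-12 * max(abs(resp), 1)) {
    out$unidentifiable <- TRUE
    warning("responses are flat: Hill parameters are unidentifiable")
    return(out)
  }
  mu_by_c <- tapply(resp, conc, mean)
  cc <- as.numeric(names(mu_by_c))
  emax0 <- max(mu_by_c)
  pos <- cc > 0
  ec50_0 <- cc[pos][which.min(abs(mu_by_c[pos] - emax0 / 2))]
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  fit <- try(
    if (free_baseline) {
      minpack.lm::nlsLM(
        resp ~ baseline + emax * conc^n / (conc^n + ec50^n),
        start = list(emax = emax0, ec50 = ec50_0, n = 1, baseline = min(mu_by_c)),
        lower = c(-Inf, 1e-9, 1e-3, -Inf), control = ctrl)
    } else {
      minpack.lm::nlsLM(
        resp ~ emax * conc^n / (conc^n + ec50^n),
        start = list(emax = emax0, ec50 = ec50_0, n = 1),
        lower = c(-Inf, 1e-9, 1e-3), control = ctrl)
    },
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    out$unidentifiable <- TRUE
    warning("Hill fit did not converge; flagged unidentifiable")
    return(out)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  out$emax <- unname(est["emax"])
  out$ec50_uM <- unname(est["ec50"])
  out$hill_n <- unname(est["n"])
  if (free_baseline) out$baseline <- unname(est["baseline"])
  out$se <- c(emax = unname(se["emax"]), ec50_uM = unname(se["ec50"]),
              hill_n = unname(se["n"]))
  out$residual_ss <- sum(stats::residuals(fit)^2)
  rng <- range(conc[conc > 0])
  if (out$ec50_uM < rng[1] || out$ec50_uM > rng[2]) {
    out$extrapolated <- TRUE
    warning(sprintf("fitted EC50 (%.3g uM) lies outside the tested range [%.3g, %.3g] uM",
                    out$ec50_uM, rng[1], rng[2]))
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$unidentifiable)) {
    cat("Hill fit: unidentifiable (flat or non-converged data)\n")
    return(invisible(x))
  }
  cat(sprintf("Hill fit: EC50 = %.3g +/- %.2g uM, n = %.3g +/- %.2g, Emax = %.3g +/- %.2g%s\n",
              x$ec50_uM, x$se[["ec50_uM"]], x$hill_n, x$se[["hill_n"]],
              x$emax, x$se[["emax"]],
              if (isTRUE(x$extrapolated)) "  [EC50 extrapolated]" else ""))
  invisible(x)
}

#' Predicted Hill response at given concentrations
#' @param object a `hill_fit`.
#' @param concentrations_uM concentrations (uM).
#' @param ... unused.
#' @export
predict.hill_fit <- function(object, concentrations_uM, ...) {
  c_n <- concentrations_uM^object$hill_n
  object$baseline + object$emax * c_n / (c_n + object$ec50_uM^object$hill_n)
}

#' 10-90% transition time of a response trace
#'
#' Measures the time between the first crossings of 10% and 90% of the
#' response amplitude after `epoch_start_s`. The pre-epoch mean defines the
#' baseline, the mean over the final 10% of the epoch defines the plateau,
#' and threshold crossings are linearly interpolated between adjacent
#' samples. The baseline is the mean over the final 10% of the pre-epoch
#' span (mirroring the plateau rule), so OFF transitions measured after an
#' ON epoch take their baseline from the preceding plateau. For a
#' single-exponential response with time constant tau the true value is
#' `tau * log(9)`.
#'
#' @param trace an [intensity_trace()] spanning the full transition.
#' @param epoch_start_s time the drug application (or removal) starts.
#' @param direction `"on"` (rising) or `"off"` (falling); checked against
#'   the sign of the measured amplitude.
#' @param epoch_end_s end of the epoch (default: end of the trace).
#' @param smooth_window optional moving-average window (samples; 0 = raw).
#' @return object of class `kinetics_result`: `t_10_90_s`, `direction`,
#'   `t10_s`, `t90_s`, `amplitude`.
#' @export
time_10_90 <- function(trace, epoch_start_s, direction = c("on", "off"),
                       epoch_end_s = NULL, smooth_window = 0L) {
  stopifnot(inherits(trace, "intensity_trace"))
  direction <- match.arg(direction)
  tt <- trace$time_s
  x <- trace$intensity
  if (smooth_window > 1) {
    x <- stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2)
    keep <- !is.na(x)
    x <- as.numeric(x[keep]); tt <- tt[keep]
  }
  if (is.null(epoch_end_s)) epoch_end_s <- tt[length(tt)]
  pre_span <- epoch_start_s - tt[1]
  pre <- tt < epoch_start_s & tt >= epoch_start_s - 0.1 * pre_span
  if (sum(pre) < 1) stop("no samples before epoch start to estimate the baseline")
  baseline <- mean(x[pre])
  base_sd <- if (sum(pre) >= 3) stats::sd(x[pre]) else 0
  span <- epoch_end_s - epoch_start_s
  plat_sel <- tt >= epoch_end_s - 0.1 * span & tt <= epoch_end_s
  if (sum(plat_sel) < 1) stop("no samples in the plateau window (final 10% of the epoch)")
  plateau <- mean(x[plat_sel])
  amp <- plateau - baseline
  if (abs(amp) < 3 * base_sd || amp == 0) {
    stop("no response: amplitude ", format(amp),
         " is indistinguishable from baseline noise (3 x s.d. = ", format(3 * base_sd), ")")
  }
  if ((amp > 0) != (direction == "on")) {
    warning("measured amplitude sign suggests direction '",
            if (amp > 0) "on" else "off", "', not '", direction, "'")
  }
  sel <- which(tt >= epoch_start_s)
  cross_time <- function(level) {
    if (amp > 0) hit <- which(x[sel] >= level) else hit <- which(x[sel] <= level)
    if (!length(hit)) stop("trace never crosses the ", format(level), " threshold")
    i <- sel[hit[1]]
    if (i == sel[1] || x[i] == x[i - 1]) return(tt[i])
    tt[i - 1] + (level - x[i - 1]) / (x[i] - x[i - 1]) * (tt[i] - tt[i - 1])
  }
  t10 <- cross_time(baseline + 0.1 * amp)
  t90 <- cross_time(baseline + 0.9 * amp)
  structure(list(t_10_90_s = t90 - t10, direction = direction,
                 t10_s = t10, t90_s = t90, amplitude = amp),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("10-90%% %s time: %.3g s (t10 = %.3g s, t90 = %.3g s, amplitude %.3g)\n",
              x$direction, x$t_10_90_s, x$t10_s, x$t90_s, x$amplitude))
  invisible(x)
}

#' Percent inverse agonism from NAM and glutamate current amplitudes
#'
#' `percent = 100 * I_NAM / (I_NAM + I_Glu)`, with both inputs the raw
#' (non-negative) response amplitudes. The statistic is invariant to a
#' common rescaling of both currents.
#'
#' @param I_NAM raw amplitude of the NAM-evoked (outward) current.
#' @param I_Glu raw amplitude of the glutamate-evoked current.
#' @return list with `I_NAM`, `I_Glu`, `percent`.
#' @export
inverse_agonism_percent <- function(I_NAM, I_Glu) {
  if (I_NAM < 0 || I_Glu < 0) stop("amplitudes must be non-negative magnitudes")
  if (I_NAM + I_Glu == 0) stop("both amplitudes are zero: percent inverse agonism undefined")
  list(I_NAM = I_NAM, I_Glu = I_Glu, percent = 100 * I_NAM / (I_NAM + I_Glu))
}

#' Normalize a response amplitude to an in-recording reference
#'
#' @param amplitude response amplitude.
#' @param reference_amplitude saturating-reference amplitude, > 0.
#' @return `amplitude / reference_amplitude`.
#' @export
normalize_response <- function(amplitude, reference_amplitude) {
  if (!is.numeric(reference_amplitude) || reference_amplitude <= 0) {
    stop("reference amplitude must be positive")
  }
  amplitude / reference_amplitude
}
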