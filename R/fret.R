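#' Construct a two-channel FRET series
#'
#' @param time_s sample times (s), strictly increasing.
#' @param donor,acceptor channel intensities (arbitrary units, >= 0).
#' @param epochs optional data.frame (label, start_s, end_s, drug,
#'   concentration_uM) of drug-application epochs; must be time-ordered,
#'   non-overlapping and within the series span.
#' @return object of class `fret_series`.
#' @export
fret_series <- function(time_s, donor, acceptor, epochs = NULL) {
  if (length(time_s) != length(donor) || length(donor) != length(acceptor)) {
    stop("time_s, donor and acceptor must have equal length")
  }
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (any(donor < 0) || any(acceptor < 0)) {
    stop("negative intensities are not allowed in a FRET series")
  }
  if (!is.null(epochs)) {
    epochs <- epochs[order(epochs$start_s), , drop = FALSE]
    if (any(epochs$end_s <= epochs$start_s)) stop("each epoch must end after it starts")
    if (nrow(epochs) > 1 && any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
      stop("epochs must be non-overlapping")
    }
    if (min(epochs$start_s) < time_s[1] || max(epochs$end_s) > time_s[length(time_s)]) {
      stop("epochs must lie within the series span")
    }
  }
  structure(list(time_s = time_s, donor = donor, acceptor = acceptor,
                 epochs = epochs),
            class = "fret_series")
}

#' Ratiometric FRET from donor and acceptor intensities
#'
#' `FRET(t) = I_Acceptor / (I_Donor + I_Acceptor)` pointwise. Samples with
#' zero total intensity are undefined and emitted as `NA` (never as 0); no
#' bleed-through or direct-excitation corrections are applied, so only
#' relative FRET changes are meaningful.
#'
#' @param series a `fret_series`.
#' @return the series with a `fret` component added.
#' @export
compute_fret <- function(series) {
  stopifnot(inherits(series, "fret_series"))
  if (any(series$donor < 0) || any(series$acceptor < 0)) {
    stop("negative intensities are not allowed")
  }
  tot <- series$donor + series$acceptor
  f <- ifelse(tot > 0, series$acceptor / tot, NA_real_)
  series$fret <- f
  series
}

#' Normalize a FRET series to its pre-drug baseline
#'
#' Divides the FRET ratio by its mean over a baseline window that must
#' precede the first drug epoch and contain at least 5 samples; the baseline
#' mean maps to 1.
#'
#' @param series a `fret_series` (FRET is computed if absent).
#' @param baseline_window_s numeric length-2 `c(start, end)` in seconds.
#' @return the series with a `fret_norm` component and a `baseline_fret`
#'   attribute-like field.
#' @export
normalize_baseline <- function(series, baseline_window_s) {
  stopifnot(inherits(series, "fret_series"), length(baseline_window_s) == 2)
  if (is.null(series$fret)) series <- compute_fret(series)
  w0 <- baseline_window_s[1]; w1 <- baseline_window_s[2]
  if (w1 <= w0) stop("baseline window must have positive length")
  if (!is.null(series$epochs) && nrow(series$epochs)) {
    first_start <- min(series$epochs$start_s)
    if (w1 > first_start) {
      stop("baseline window [", w0, ", ", w1,
           "] overlaps a drug epoch starting at ", first_start, " s")
    }
  }
  sel <- series$time_s >= w0 & series$time_s <= w1
  if (sum(sel) < 5) stop("baseline window contains ", sum(sel), " samples; need >= 5")
  base <- mean(series$fret[sel], na.rm = TRUE)
  if (!is.finite(base) || base <= 0) stop("baseline FRET is zero or undefined")
  series$fret_norm <- series$fret / base
  series$baseline_fret <- base
  series
}

# mean of the baseline-normalized FRET over the last 25% of an epoch
.epoch_plateau <- function(series, epoch) {
  sel <- series$time_s >= epoch$start_s & series$time_s < epoch$end_s
  n <- sum(sel)
  if (n < 20) {
    stop("epoch '", epoch$label, "' contains ", n, " samples; need >= 20")
  }
  tcut <- epoch$end_s - 0.25 * (epoch$end_s - epoch$start_s)
  plat <- sel & series$time_s >= tcut
  if (sum(plat) < 5) stop("plateau window of epoch '", epoch$label, "' has < 5 samples")
  mean(series$fret_norm[plat], na.rm = TRUE)
}

#' Drug-induced FRET response amplitude for one epoch
#'
#' The plateau is the mean of the baseline-normalized FRET over the last
#' 25% of the epoch; `delta_fret_norm = plateau - 1`. When a reference
#' epoch (saturating reference drug applied within the same recording) is
#' given, the response is also expressed as a fraction of the reference
#' response.
#'
#' @param series a baseline-normalized `fret_series` (see
#'   [normalize_baseline()]).
#' @param epoch_label label of the epoch to quantify.
#' @param reference_label optional label of the in-recording reference epoch.
#' @return object of class `fret_response` with `label`, `delta_fret_norm`,
#'   and `ref_normalized` (NA when no reference given).
#' @export
response_amplitude <- function(series, epoch_label, reference_label = NULL) {
  stopifnot(inherits(series, "fret_series"))
  if (is.null(series$fret_norm)) stop("series must be baseline-normalized first")
  if (is.null(series$epochs)) stop("series carries no epoch table")
  pick <- function(lbl) {
    i <- which(series$epochs$label == lbl)
    if (!length(i)) stop("no epoch labeled '", lbl, "'")
    series$epochs[i[1], , drop = FALSE]
  }
  delta <- .epoch_plateau(series, pick(epoch_label)) - 1
  refn <- NA_real_
  if (!is.null(reference_label)) {
    dref <- .epoch_plateau(series, pick(reference_label)) - 1
    if (dref == 0) stop("reference epoch '", reference_label, "' has zero response")
    refn <- delta / dref
  }
  structure(list(label = epoch_label, delta_fret_norm = delta,
                 ref_normalized = refn),
            class = "fret_response")
}

#' Donor recovery after acceptor photobleaching
#'
#' Fractional increase of donor fluorescence after destroying the acceptor:
#' `recovery = (I_D_after - I_D_before) / I_D_before`. Positive recovery
#' indicates energy transfer was present. For a conserved-intensity
#' two-fluorophore pair with FRET ratio E and complete acceptor bleaching,
#' `recovery = E / (1 - E)`.
#'
#' @param I_D_before,I_D_after donor intensity before/after the bleach.
#' @param I_A_before,I_A_after acceptor intensity before/after the bleach.
#' @return list with `recovery`, `acceptor_loss` (fraction of acceptor
#'   signal lost), and `acceptor_bleached` (TRUE when loss >= 80%; when
#'   FALSE a warning is raised but the value is still returned).
#' @export
donor_recovery <- function(I_D_before, I_D_after, I_A_before, I_A_after) {
  if (I_D_before <= 0 || I_A_before < 0) stop("pre-bleach intensities invalid")
  loss <- 1 - I_A_after / I_A_before
  ok <- is.finite(loss) && loss >= 0.80
  if (!ok) {
    warning(sprintf("acceptor not substantially bleached (%.0f%% loss < 80%%); recovery returned anyway",
                    100 * loss))
  }
  list(recovery = (I_D_after - I_D_before) / I_D_before,
       acceptor_loss = loss, acceptor_bleached = ok)
}
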