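#' Binomial labeling model for photobleaching stoichiometry
#'
#' Constructs the forward model that links the monomer/dimer composition of a
#' single-molecule pulldown sample to the distribution of observed
#' photobleaching step counts. Each subunit of a complex carries a functional
#' fluorophore independently with probability `p` (the SNAP-tag labeling
#' efficiency); complexes with no label are invisible and never appear as
#' spots. With probability `b` a visible spot additionally contains one
#' extra, labeled monomer (chance colocalization of two molecules within a
#' diffraction-limited spot, plus antibody/NeutrAvidin bivalency, lumped into
#' a single background term).
#'
#' @param f_dimer fraction of complexes that are dimers, in \[0, 1\].
#' @param p per-subunit labeling efficiency, in \[0, 1\]. Default 0.80.
#' @param b background colocalization probability, in \[0, 1\]. Default 0
#'   (set to 0.05-0.10 to model the empirical two-step background).
#' @return an object of class `stoichiometry_model`.
#' @export
stoichiometry_model <- function(f_dimer, p = 0.80, b = 0) {
  if (!is.numeric(f_dimer) || length(f_dimer) != 1L || is.na(f_dimer) ||
      f_dimer < -1e-9 || f_dimer > 1 + 1e-9) {
    stop("invalid StoichiometryModel: f_dimer must be a single number in [0, 1], got ",
         format(f_dimer))
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("invalid StoichiometryModel: labeling efficiency p must be in [0, 1], got ",
         format(p))
  }
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0 || b > 1) {
    stop("invalid StoichiometryModel: background probability b must be in [0, 1], got ",
         format(b))
  }
  f_dimer <- min(max(f_dimer, 0), 1)
  structure(
    list(f_dimer = f_dimer, f_monomer = 1 - f_dimer, p = p, b = b),
    class = "stoichiometry_model"
  )
}

#' @export
print.stoichiometry_model <- function(x, ...) {
  cat(sprintf(
    "Stoichiometry model: f_dimer = %.4f, labeling efficiency p = %.3f, background b = %.3f\n",
    x$f_dimer, x$p, x$b))
  invisible(x)
}

#' Forward distribution over photobleaching step categories
#'
#' Probability that a *visible* spot bleaches in 1, 2, or >= 3 steps under
#' the binomial labeling model. A monomer is visible with probability `p` and
#' always bleaches in one step. A dimer is visible with probability
#' `2p - p^2` and, conditional on visibility, bleaches in two steps with
#' probability `p^2 / (2p - p^2)`. A background event (probability `b`)
#' attaches one extra labeled monomer, shifting the category up by one
#' (1 -> 2, 2 -> 3plus).
#'
#' @param model a [stoichiometry_model()].
#' @return named numeric vector of probabilities over `c("1", "2", "3plus")`,
#'   summing to 1.
#' @export
forward_distribution <- function(model) {
  stopifnot(inherits(model, "stoichiometry_model"))
  p <- model$p
  b <- model$b
  f <- model$f_dimer
  if (p == 0) {
    stop("labeling efficiency p = 0: no complex is visible, the step-count distribution is undefined")
  }
  vis_dimer <- 2 * p - p^2        # P(dimer has >= 1 label)
  theta_vis <- f * vis_dimer + (1 - f) * p
  w_dimer <- f * vis_dimer / theta_vis   # P(dimer | visible)
  # base categories before background
  p2_base <- w_dimer * p^2 / vis_dimer   # visible dimer with both labels
  p1_base <- 1 - p2_base
  probs <- c(
    "1"     = (1 - b) * p1_base,
    "2"     = (1 - b) * p2_base + b * p1_base,
    "3plus" = b * p2_base
  )
  probs
}

#' Closed-form inversion of the two-step fraction to a dimer fraction
#'
#' Solves the background-free (`b = 0`) forward model
#' `theta2 = f p^2 / (f (2p - p^2) + (1 - f) p)` for the dimer fraction `f`,
#' giving `f = theta2 / (p + theta2 (p - 1))`. This is the standard
#' labeling-efficiency correction used to turn an observed two-step
#' photobleaching percentage into a dimer fraction.
#'
#' @param theta2 observed fraction of accepted spots bleaching in two steps,
#'   in \[0, p/(2-p)\] (the pure-dimer ceiling).
#' @param p labeling efficiency, in (0, 1\].
#' @return dimer fraction in \[0, 1\].
#' @examples
#' invert_dimer_fraction(0.45, 0.8)  # ~0.634, i.e. "~60%" of complexes are dimers
#' @export
invert_dimer_fraction <- function(theta2, p = 0.80) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("labeling efficiency p must be in (0, 1], got ", format(p))
  }
  if (!is.numeric(theta2) || length(theta2) != 1L || is.na(theta2) || theta2 < 0) {
    stop("theta2 must be a single non-negative number")
  }
  ceiling2 <- p / (2 - p)
  if (theta2 > ceiling2 + 1e-12) {
    stop(sprintf(
      "two-step fraction %.4f exceeds the pure-dimer ceiling p/(2-p) = %.4f at p = %.3f",
      theta2, ceiling2, p))
  }
  f <- theta2 / (p + theta2 * (p - 1))
  min(max(f, 0), 1)
}

# multinomial log-likelihood of step-category counts at dimer fraction f;
# categories with model probability 0 must carry zero counts (checked upstream)
.stoich_loglik <- function(f, counts, p, b) {
  pr <- forward_distribution(stoichiometry_model(f, p = p, b = b))
  keep <- counts > 0
  sum(counts[keep] * log(pr[keep]))
}

#' Maximum-likelihood dimer fraction from step-category counts
#'
#' Maximizes the multinomial likelihood of observed step-count categories
#' under [forward_distribution()] over the dimer fraction, with the labeling
#' efficiency `p` and background `b` held fixed (a three-category table
#' cannot identify all three parameters jointly). The 95% confidence
#' interval is obtained by profile likelihood (deviance cutoff 3.84).
#'
#' When `b = 0` the model assigns probability zero to the `3plus` category;
#' any observed `3plus` counts (rare step-detection artifacts) are then
#' excluded with a warning and the likelihood renormalized over the
#' remaining categories.
#'
#' @param counts named integer vector with names among
#'   `c("1", "2", "3plus")`; total must be at least 50.
#' @param p labeling efficiency (fixed, known).
#' @param b background colocalization probability (fixed, known).
#' @param conf confidence level for the profile interval. Default 0.95.
#' @return an object of class `stoichiometry_estimate` with fields
#'   `f_dimer_hat`, `ci_low`, `ci_high`, `log_likelihood`, `method`,
#'   `boundary` (TRUE when the estimate sits on 0 or 1).
#' @export
fit_ml <- function(counts, p = 0.80, b = 0, conf = 0.95) {
  cats <- c("1", "2", "3plus")
  full <- setNames(numeric(3), cats)
  if (is.null(names(counts))) stop("counts must be named with categories among ", paste(cats, collapse = ", "))
  bad <- setdiff(names(counts), cats)
  if (length(bad)) stop("unknown count categories: ", paste(bad, collapse = ", "))
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != round(full))) stop("counts must be non-negative integers")
  if (sum(full) < 50) stop("need at least 50 spots for maximum-likelihood inversion, got ", sum(full))
  if (b == 0 && full["3plus"] > 0) {
    warning(sprintf(
      "b = 0 assigns probability 0 to the 3plus category; excluding %d 3plus spot(s) from the likelihood",
      as.integer(full["3plus"])))
    full["3plus"] <- 0
  }
  ll <- function(f) .stoich_loglik(f, full, p, b)
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-10)
  # optimize() never returns an exact endpoint; compare against the boundaries
  cand_f <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll(0), ll(1))
  best <- which.max(cand_ll)
  f_hat <- cand_f[best]
  ll_hat <- cand_ll[best]
  boundary <- f_hat <= 1e-9 || f_hat >= 1 - 1e-9
  if (boundary) f_hat <- round(f_hat)

  cut <- stats::qchisq(conf, df = 1) / 2   # logLik drop at the CI edge
  dev <- function(f) ll_hat - ll(f) - cut
  ci_low <- 0
  ci_high <- 1
  if (f_hat > 0 && dev(0) > 0) {
    ci_low <- stats::uniroot(dev, c(0, f_hat), tol = 1e-9)$root
  }
  if (f_hat < 1 && dev(1) > 0) {
    ci_high <- stats::uniroot(dev, c(f_hat, 1), tol = 1e-9)$root
  }
  structure(
    list(f_dimer_hat = f_hat, ci_low = ci_low, ci_high = ci_high,
         log_likelihood = ll_hat, method = "maximum_likelihood",
         boundary = boundary, p = p, b = b, n = sum(full)),
    class = "stoichiometry_estimate"
  )
}

#' @export
print.stoichiometry_estimate <- function(x, ...) {
  cat(sprintf(
    "Dimer fraction (ML): %.3f  [95%% CI %.3f-%.3f]  (~%d%% to the nearest ten percent), n = %d spots%s\n",
    x$f_dimer_hat, x$ci_low, x$ci_high, round(x$f_dimer_hat * 10) * 10, x$n,
    if (isTRUE(x$boundary)) "  [boundary estimate, one-sided CI]" else ""))
  invisible(x)
}

#' Compare per-movie two-step percentages across conditions
#'
#' Movie is the unit of replication. Two groups are compared with an
#' unpaired two-sided t test; three or more with a one-way ANOVA.
#'
#' @param groups a named (or unnamed) list of numeric vectors, one per
#'   condition, each holding per-movie two-step percentages (>= 2 movies each).
#' @return list with `statistic`, `p_value`, `test` ("t" or "anova"),
#'   `df`, and per-group means.
#' @export
compare_conditions <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop("every group needs at least 2 movies; group(s) ",
         paste(which(sizes < 2), collapse = ", "), " have fewer")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  if (length(groups) == 2) {
    ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    out <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test = "t", df = unname(ht$parameter), group_means = means)
  } else {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), sizes))
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    out <- list(statistic = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
                test = "anova", df = c(tab[1, "Df"], tab[2, "Df"]),
                group_means = means)
  }
  out
}
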