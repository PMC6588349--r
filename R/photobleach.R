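#' Robust noise estimate for a fluorescence trace
#'
#' Estimates the white-noise standard deviation from the median absolute
#' deviation of the first differences, scaled by `1/(sqrt(2) * 0.6745)`.
#' The scaling makes the estimate consistent for Gaussian noise while the
#' median makes it insensitive to the sparse bleaching steps.
#'
#' @param trace an [intensity_trace()] (or numeric vector of intensities).
#' @return estimated noise s.d. (0 for a constant trace).
#' @export
estimate_noise <- function(trace) {
  x <- if (inherits(trace, "intensity_trace")) trace$intensity else as.numeric(trace)
  d <- diff(x)
  # stats::mad already applies the 1/0.6745 consistency factor
  stats::mad(d) / sqrt(2)
}

# SSE of segment x[a..b] around its mean, from precomputed cumsums
.seg_sse <- function(cs, cs2, a, b) {
  s <- cs[b + 1L] - cs[a]
  s2 <- cs2[b + 1L] - cs2[a]
  max(s2 - s^2 / (b - a + 1L), 0)
}

# best single change point in x[a..b]: maximal SSE reduction, with up-steps
# larger than `up_tol` disallowed. Returns NULL when no admissible split gains.
.best_split <- function(cs, cs2, a, b, up_tol) {
  len <- b - a + 1L
  if (len < 2L) return(NULL)
  idx <- a:(b - 1L)                       # split after these indices
  nl <- idx - a + 1L
  nr <- len - nl
  sl <- cs[idx + 1L] - cs[a]
  sr <- (cs[b + 1L] - cs[a]) - sl
  red <- sl^2 / nl + sr^2 / nr - (sl + sr)^2 / len
  if (is.finite(up_tol)) {
    red[(sr / nr - sl / nl) > up_tol] <- -Inf
  }
  i <- which.max(red)
  if (!is.finite(red[i]) || red[i] <= 0) return(NULL)
  list(pos = idx[i], gain = red[i])
}

# coordinate-descent refinement of change-point positions: each boundary is
# re-placed at the best split of the stretch between its neighbors. Fixes
# off-by-a-frame placements left by greedy binary splitting, which would
# otherwise invite a spurious extra step.
.refine_bounds <- function(cs, cs2, bounds, n, up_tol, sweeps = 3L) {
  if (length(bounds) < 1L) return(bounds)
  for (s in seq_len(sweeps)) {
    changed <- FALSE
    for (j in seq_along(bounds)) {
      a <- if (j == 1L) 1L else bounds[j - 1L] + 1L
      b <- if (j == length(bounds)) n else bounds[j + 1L]
      sp <- .best_split(cs, cs2, a, b, up_tol)
      if (!is.null(sp) && sp$pos != bounds[j]) {
        bounds[j] <- sp$pos
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bounds
}

# total SSE of the piecewise-constant fit defined by the boundary set
.bounds_sse <- function(cs, cs2, bounds, n) {
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  sum(vapply(seq_along(starts),
             function(i) .seg_sse(cs, cs2, starts[i], ends[i]), numeric(1)))
}

#' Detect photobleaching steps in an intensity trace
#'
#' Piecewise-constant least-squares segmentation by recursive binary
#' splitting of the best change point, with the model order chosen to
#' minimize `SSE(k) + penalty_scale * k * noise_sd_hat^2 * log(N)` (a
#' BIC-like penalty). In photobleaching mode candidate splits that would
#' create an up-step larger than `2 * noise_sd_hat` are rejected, so fitted
#' levels decrease along the trace.
#'
#' @param trace an [intensity_trace()].
#' @param max_steps maximum number of steps considered (default 6).
#' @param penalty_scale positive penalty multiplier (default 2.0).
#' @param monotone enforce the photobleaching (decreasing-level) constraint.
#'   Default TRUE.
#' @return object of class `step_fit` with fields `trace_id`, `n_steps`,
#'   `step_times_s`, `levels` (length `n_steps + 1`), `sse`, `noise_sd_hat`.
#' @export
detect_steps <- function(trace, max_steps = 6L, penalty_scale = 2.0, monotone = TRUE) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$intensity
  n <- length(x)
  if (n < 10L) stop("trace '", trace$trace_id, "' too short for step detection (", n, " samples)")
  if (max_steps < 1L) stop("max_steps must be >= 1")
  if (penalty_scale <= 0) stop("penalty_scale must be positive")
  sigma <- estimate_noise(trace)
  up_tol <- if (monotone) 2 * sigma + 1e-9 * max(abs(x), 1) else Inf

  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  bounds_by_k <- list(integer(0))
  sse_k <- .seg_sse(cs, cs2, 1L, n)
  bounds <- integer(0)
  while (length(bounds) < max_steps) {
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    cand <- lapply(seq_along(starts),
                   function(i) .best_split(cs, cs2, starts[i], ends[i], up_tol))
    gains <- vapply(cand, function(cc) if (is.null(cc)) -Inf else cc$gain, numeric(1))
    j <- which.max(gains)
    if (!is.finite(gains[j]) || gains[j] <= 0) break
    bounds <- .refine_bounds(cs, cs2, sort(c(bounds, cand[[j]]$pos)), n, up_tol)
    bounds_by_k[[length(bounds_by_k) + 1L]] <- bounds
    sse_k <- c(sse_k, .bounds_sse(cs, cs2, bounds, n))
  }

  kk <- seq_along(sse_k) - 1L
  score <- sse_k + penalty_scale * kk * sigma^2 * log(n)
  tol <- 1e-9 * max(abs(score[1]), 1)
  k_star <- kk[which(score <= min(score) + tol)[1]]
  bounds <- bounds_by_k[[k_star + 1L]]
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  levels <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  sse <- sum(vapply(seq_along(starts),
                    function(i) .seg_sse(cs, cs2, starts[i], ends[i]), numeric(1)))
  structure(
    list(trace_id = trace$trace_id, n_steps = k_star,
         step_times_s = if (k_star > 0) trace$time_s[bounds + 1L] else numeric(0),
         levels = levels, sse = sse, noise_sd_hat = sigma),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit '%s': %d step(s) at [%s] s, levels [%s], sigma_hat = %.3g\n",
              x$trace_id, x$n_steps,
              paste(signif(x$step_times_s, 4), collapse = ", "),
              paste(signif(x$levels, 4), collapse = ", "),
              x$noise_sd_hat))
  invisible(x)
}

#' Classify a spot by its fitted step count
#'
#' Accepted categories are "1", "2" and "3plus". A spot is "rejected" when
#' no step was found, when the final level is not within `3 * noise_sd_hat`
#' of zero (the molecule did not fully bleach), or when any fitted step
#' height is below `3 * noise_sd_hat` (indistinguishable from noise).
#'
#' @param fit a `step_fit` from [detect_steps()].
#' @return one of `"1"`, `"2"`, `"3plus"`, `"rejected"`.
#' @export
classify_spot <- function(fit) {
  stopifnot(inherits(fit, "step_fit"))
  if (fit$n_steps == 0L) return("rejected")
  scale <- max(abs(fit$levels), 1)
  tol <- 3 * fit$noise_sd_hat + 1e-8 * scale
  if (abs(fit$levels[length(fit$levels)]) > tol) return("rejected")
  drops <- -diff(fit$levels)
  if (any(drops < 3 * fit$noise_sd_hat - 1e-8 * scale)) return("rejected")
  if (fit$n_steps == 1L) "1" else if (fit$n_steps == 2L) "2" else "3plus"
}

#' Summarize step categories for one movie
#'
#' @param categories character vector of per-spot categories from
#'   [classify_spot()].
#' @param movie_id identifier.
#' @return object of class `movie_summary` with per-category `counts`,
#'   `pct_two_step` among accepted spots, and `n_accepted`.
#' @export
summarize_movie <- function(categories, movie_id = "movie1") {
  cats <- c("1", "2", "3plus", "rejected")
  bad <- setdiff(unique(categories), cats)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  counts <- vapply(cats, function(cc) sum(categories == cc), numeric(1))
  n_acc <- sum(counts[c("1", "2", "3plus")])
  if (n_acc == 0) stop("movie '", movie_id, "' has zero accepted spots")
  structure(
    list(movie_id = movie_id, counts = counts,
         pct_two_step = 100 * counts[["2"]] / n_acc, n_accepted = n_acc),
    class = "movie_summary"
  )
}

#' @export
print.movie_summary <- function(x, ...) {
  cat(sprintf("Movie '%s': %d accepted spots (1-step %d, 2-step %d, >=3-step %d; %d rejected), %.1f%% two-step\n",
              x$movie_id, x$n_accepted, x$counts[["1"]], x$counts[["2"]],
              x$counts[["3plus"]], x$counts[["rejected"]], x$pct_two_step))
  invisible(x)
}

#' Aggregate per-movie two-step percentages for one condition
#'
#' The movie is the statistical unit: the condition-level mean and s.e.m.
#' are computed across movies; pooled per-category spot counts are reported
#' alongside.
#'
#' @param movies list of `movie_summary` objects.
#' @return list with `mean_pct_two_step`, `sem`, `n_movies`, `pooled_counts`,
#'   and `sem_defined` (FALSE for a single movie, where s.e.m. is undefined).
#' @export
aggregate_condition <- function(movies) {
  if (!is.list(movies) || !length(movies) ||
      !all(vapply(movies, inherits, logical(1), "movie_summary"))) {
    stop("movies must be a non-empty list of movie_summary objects")
  }
  pct <- vapply(movies, function(m) m$pct_two_step, numeric(1))
  pooled <- Reduce(`+`, lapply(movies, function(m) m$counts))
  n <- length(movies)
  if (n == 1) {
    warning("single movie: s.e.m. undefined")
    sem <- NA_real_
  } else {
    sem <- stats::sd(pct) / sqrt(n)
  }
  list(mean_pct_two_step = mean(pct), sem = sem, n_movies = n,
       pooled_counts = pooled, sem_defined = n > 1)
}
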