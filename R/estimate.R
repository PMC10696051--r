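#' Threshold-crossing times of gridded trajectories
#'
#' For each replicate trajectory, finds the first grid interval in which the
#' signal reaches `threshold` and refines the crossing time by linear
#' interpolation between the bracketing samples. Replicates that never reach
#' the threshold are excluded; their count is recorded in the `n_excluded`
#' attribute (with a warning when more than 10% are excluded).
#'
#' @param trajectories A tibble with one row per (replicate, time point), as
#'   returned by [sample_trajectories()].
#' @param threshold Signal level defining the passage event.
#' @param time_col,value_col Column names for time and signal.
#' @param replicate_col Column identifying replicates.
#' @return An `fpt_sample` tibble (`replicate`, `fpt_hours`), with attributes
#'   `n_excluded` and `threshold`.
#' @export
threshold_crossing_times <- function(trajectories, threshold,
                                     time_col = "time_hours",
                                     value_col = "abundance",
                                     replicate_col = "replicate") {
  stopifnot(is.data.frame(trajectories),
            all(c(time_col, value_col, replicate_col) %in% names(trajectories)))
  sp <- split(trajectories, trajectories[[replicate_col]])
  cross_one <- function(d) {
    tt <- d[[time_col]]; y <- d[[value_col]]
    o <- order(tt); tt <- tt[o]; y <- y[o]
    i <- which(y >= threshold)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    if (i == 1) return(tt[1])
    # linear interpolation between the bracketing samples
    tt[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
  }
  times <- vapply(sp, cross_one, numeric(1))
  reps <- names(sp)
  excluded <- is.na(times)
  if (all(excluded)) stop("no replicate reaches the threshold", call. = FALSE)
  if (mean(excluded) > 0.1) {
    warning(sprintf("%d of %d replicates (%.0f%%) never reach the threshold",
                    sum(excluded), length(excluded), 100 * mean(excluded)),
            call. = FALSE)
  }
  out <- tibble::tibble(replicate = reps[!excluded],
                        fpt_hours = unname(times[!excluded]))
  class(out) <- c("fpt_sample", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "n_excluded") <- sum(excluded)
  attr(out, "n_reps") <- nrow(out)
  out
}

fpt_times <- function(sample) {
  if (is.data.frame(sample)) {
    stopifnot("fpt_hours" %in% names(sample))
    sample$fpt_hours
  } else {
    as.numeric(sample)
  }
}

#' Temporal standard deviation with a percentile-bootstrap confidence interval
#'
#' The TSD is the sample standard deviation (denominator n - 1) of replicate
#' first-passage times; uncertainty is quantified with a percentile bootstrap
#' over resamples of the replicates.
#'
#' @param sample An `fpt_sample` (or any data frame with an `fpt_hours`
#'   column, or a numeric vector of times in hours).
#' @param level Confidence level in (0, 1); 0.95 is conventional for
#'   simulation summaries, 0.68 for empirical TSDs.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed (restored afterwards).
#' @return An object of class `tsd_estimate`; see [tidy.tsd_estimate()].
#' @export
tsd_with_ci <- function(sample, level = 0.95, n_boot = 1000, seed = NULL) {
  x <- fpt_times(sample)
  if (length(x) < 2) stop("at least 2 replicates are required", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  tsd <- stats::sd(x)
  boot <- vapply(seq_len(n_boot),
                 function(i) stats::sd(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(tsd = tsd, ci_low = min(ci[1], tsd), ci_high = max(ci[2], tsd),
                 level = level, n_boot = n_boot, n_replicates = length(x),
                 seed = seed),
            class = "tsd_estimate")
}

#' @export
print.tsd_estimate <- function(x, ...) {
  cat(sprintf("<tsd_estimate> TSD = %.4g h [%.4g, %.4g] (%d%% CI, %d replicates, %d resamples)\n",
              x$tsd, x$ci_low, x$ci_high, round(100 * x$level),
              x$n_replicates, x$n_boot))
  invisible(x)
}

#' Tidy a TSD estimate
#' @param x A `tsd_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `tsd`, `ci_low`, `ci_high`, `level`,
#'   `n_replicates`, `n_boot`.
#' @method tidy tsd_estimate
#' @export
tidy.tsd_estimate <- function(x, ...) {
  tibble::tibble(tsd = x$tsd, ci_low = x$ci_low, ci_high = x$ci_high,
                 level = x$level, n_replicates = x$n_replicates,
                 n_boot = x$n_boot)
}

#' @importFrom generics glance
#' @method glance tsd_estimate
#' @export
glance.tsd_estimate <- function(x, ...) tidy(x)

#' Noise-based growth-rate estimator
#'
#' Inverts the exact simple-birth-process relation between TSD, growth rate
#' and inoculum size:
#' \deqn{\hat\mu = \frac{1}{\sigma_t}
#'       \left[\sum_{n=n_0}^{\Omega-1} \frac{1}{n^2}\right]^{1/2}.}
#' The estimate assumes growth follows the simple birth process with no
#' other noise sources; dispersive noise (which inflates the measured TSD)
#' makes \eqn{\hat\mu} a lower bound on the true growth rate, focusing noise
#' an upper bound.
#'
#' @param tsd Measured temporal standard deviation, hours (> 0). May also be
#'   a `tsd_estimate`, in which case the CI endpoints are propagated.
#' @param n0 Inoculum size (integer >= 1); for Poisson inoculation use the
#'   rounded zero-truncated mean.
#' @param omega Threshold population size (> n0).
#' @return Estimated growth rate, 1/hour (a tibble with CI columns when
#'   `tsd` is a `tsd_estimate`).
#' @export
infer_growth_rate <- function(tsd, n0, omega) {
  pr <- passage_problem(n0, omega)
  root <- sqrt(harmonic_partial(pr$n0, pr$omega, 2))
  if (inherits(tsd, "tsd_estimate")) {
    return(tibble::tibble(mu_hat = root / tsd$tsd,
                          ci_low = root / tsd$ci_high,
                          ci_high = root / tsd$ci_low,
                          level = tsd$level))
  }
  if (any(tsd <= 0)) stop("`tsd` must be positive", call. = FALSE)
  root / tsd
}

#' Precision of the growth-rate estimate versus number of replicates
#'
#' For each subsample size m, bootstrap-resamples m first-passage times,
#' computes the TSD-based growth-rate estimate on each resample, and reports
#' the median and percentile interval. Quantifies how many replicate growth
#' trajectories are needed for a given precision; the interval width shrinks
#' roughly as \eqn{1/\sqrt{m}}.
#'
#' @param sample An `fpt_sample` (or numeric vector of times, hours).
#' @param n0 Inoculum size used in the estimator.
#' @param omega Threshold population size.
#' @param subsample_sizes Vector of subsample sizes (each >= 2, at most the
#'   number of replicates).
#' @param n_boot Bootstrap resamples per size (default 5000).
#' @param level Interval level (default 0.68).
#' @param seed Optional integer seed.
#' @return A tibble: `m`, `mu_hat` (median), `ci_low`, `ci_high`, `level`.
#' @export
precision_curve <- function(sample, n0, omega, subsample_sizes,
                            n_boot = 5000, level = 0.68, seed = NULL) {
  x <- fpt_times(sample)
  if (any(subsample_sizes < 2)) stop("subsample sizes must be >= 2", call. = FALSE)
  if (any(subsample_sizes > length(x))) {
    stop("subsample sizes cannot exceed the number of replicates", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  root <- sqrt(harmonic_partial(n0, omega, 2))
  alpha <- (1 - level) / 2
  purrr::map_dfr(subsample_sizes, function(m) {
    mu <- vapply(seq_len(n_boot), function(i) {
      root / stats::sd(x[sample.int(length(x), m, replace = TRUE)])
    }, numeric(1))
    mu <- mu[is.finite(mu)]
    qs <- unname(stats::quantile(mu, c(0.5, alpha, 1 - alpha)))
    tibble::tibble(m = m, mu_hat = qs[1], ci_low = qs[2], ci_high = qs[3],
                   level = level)
  })
}

#' Convert a TSD from hours to division-time units
#'
#' A division time is \eqn{\ln 2/\mu}, so a TSD of `tsd` hours corresponds to
#' `tsd * mu / ln 2` division times. Plotting TSDs in division-time units
#' collapses organisms with different growth rates onto a common curve.
#'
#' @param tsd_hours TSD in hours.
#' @param mu Growth rate, 1/hour.
#' @return TSD in division times.
#' @export
tsd_in_division_times <- function(tsd_hours, mu) {
  tsd_hours * mu / log(2)
}
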