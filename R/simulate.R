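new_fpt_sample <- function(times, inocula, model, threshold, seed = NULL) {
  out <- tibble::tibble(
    replicate = seq_along(times),
    inoculum = inocula,
    fpt_hours = times
  )
  class(out) <- c("fpt_sample", class(out))
  attr(out, "model") <- model
  attr(out, "threshold") <- threshold
  attr(out, "seed") <- seed
  attr(out, "n_reps") <- length(times)
  out
}

#' @export
print.fpt_sample <- function(x, ...) {
  cat(sprintf("<fpt_sample> model '%s', threshold %g, %d replicates\n",
              attr(x, "model"), attr(x, "threshold"), attr(x, "n_reps")))
  NextMethod()
}

draw_inocula <- function(inoculum, n_reps) {
  stopifnot(inherits(inoculum, "inoculum_law"))
  if (inoculum$kind == "exact") rep.int(as.integer(inoculum$value), n_reps)
  else rztpois(n_reps, inoculum$value)
}

#' Sample first-passage times of the simple birth process
#'
#' Exact FPT sampling without event-by-event simulation: a Yule population of
#' size \eqn{n} waits an Exp(\eqn{\mu n}) time before its next division and
#' waiting times are independent, so each replicate's first-passage time at
#' \eqn{\Omega} is \eqn{\sum_{n=k}^{\Omega-1} \mathrm{Exp}(\mu n)} given
#' inoculum \eqn{k}. Inocula are exact or zero-truncated Poisson (inverse-CDF
#' draws). Reproducible under `seed`.
#'
#' @param params [growth_params()] or rate, 1/hour.
#' @param inoculum An [inoculum_law()].
#' @param omega Threshold population size.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An `fpt_sample` tibble: `replicate`, `inoculum`, `fpt_hours`.
#' @export
sample_sbp_fpt <- function(params, inoculum, omega, n_reps, seed = NULL) {
  mu <- as_growth_params(params)$mu
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  ks <- draw_inocula(inoculum, n_reps)
  if (any(ks >= omega)) {
    warning("some inocula at or above the threshold; their FPT is 0", call. = FALSE)
  }
  times <- vapply(ks, function(k) {
    if (k >= omega) return(0)
    sum(stats::rexp(omega - k, rate = mu * seq.int(k, omega - 1)))
  }, numeric(1))
  new_fpt_sample(times, ks, model = paste0("sbp+", inoculum$kind),
                 threshold = omega, seed = seed)
}

#' Sample first-passage times of age-structured (Bellman-Harris) growth
#'
#' Event-queue simulation of an age-structured branching process: each
#' individual draws an i.i.d. division time from `law` (k-stage Erlang,
#' i.e. rescaled chi-squared with 2k degrees of freedom, or exponential),
#' then is replaced by two newborns with fresh draws. Inoculated individuals
#' are assumed to sit at a random point of their division cycle; by default
#' their first division is drawn uniformly on \eqn{[0, \ln 2/\mu_{eff}]}
#' with \eqn{\mu_{eff} = \ln 2 / \bar\tau} the rate matched to the mean
#' division time \eqn{\bar\tau}. The FPT is recorded at the division event
#' at which the count first reaches `omega` (counts change only at events).
#'
#' @param law A [division_time_law()].
#' @param inoculum An [inoculum_law()].
#' @param omega Threshold population size.
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @param initial_phase `"uniform"` (default), `"exponential"` (memoryless
#'   residual, Exp(mean); with a 1-stage law this makes the model identical
#'   to the simple birth process), or `"zero"` (newborn founders).
#' @param event_budget Maximum division events per replicate; replicates
#'   exceeding it return `NA` with a warning.
#' @return An `fpt_sample` tibble with `fpt_hours`.
#' @export
sample_age_structured_fpt <- function(law, inoculum, omega, n_reps, seed = NULL,
                                      initial_phase = c("uniform", "exponential", "zero"),
                                      event_budget = 1e7) {
  stopifnot(inherits(law, "division_time_law"))
  initial_phase <- match.arg(initial_phase)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  ks <- draw_inocula(inoculum, n_reps)
  if (any(ks > omega)) stop("inoculum exceeds threshold", call. = FALSE)
  mean_h <- law$mean_division_time / 60
  mu_eff <- log(2) / mean_h
  phase_window <- log(2) / mu_eff  # = mean division time, hours
  times <- bh_fpt_cpp(as.integer(ks), omega, law$stages, mean_h,
                      initial_phase, phase_window, event_budget)
  if (anyNA(times)) {
    warning(sum(is.na(times)), " replicate(s) exceeded the event budget", call. = FALSE)
  }
  new_fpt_sample(times, ks, model = paste0("age", law$stages, "+", inoculum$kind),
                 threshold = omega, seed = seed)
}

sbp_event_times <- function(mu, k, cap) {
  if (k >= cap) return(numeric(0))
  cumsum(stats::rexp(cap - k, rate = mu * seq.int(k, cap - 1)))
}

#' Sample abundance trajectories on a regular time grid
#'
#' Abundance-versus-time paths for the three growth models, sampled on a
#' regular grid. Stochastic paths are piecewise constant between division
#' events (pure birth: non-decreasing). Stochastic growth is simulated
#' exactly up to `stochastic_cap` individuals and continued deterministically
#' at the model's exponential rate beyond it; temporal variation accumulates
#' at small population sizes, so crossing statistics at thresholds well below
#' the cap are exact and above it inherit the variation accrued by the cap.
#'
#' @param growth `"sbp"`, `"age"` or `"deterministic"`.
#' @param inoculum An [inoculum_law()].
#' @param params [growth_params()] or rate, 1/hour (for `"sbp"` and
#'   `"deterministic"`).
#' @param law A [division_time_law()] (for `"age"`).
#' @param horizon Trajectory length, hours.
#' @param grid_step_min Grid spacing, minutes.
#' @param n_reps Number of replicate trajectories.
#' @param stochastic_cap Population size beyond which growth is continued
#'   deterministically.
#' @param seed Optional integer seed.
#' @param initial_phase Initial-phase convention for `"age"`; see
#'   [sample_age_structured_fpt()].
#' @return A tibble: `replicate`, `inoculum`, `time_hours`, `abundance`.
#' @export
sample_trajectories <- function(growth = c("sbp", "age", "deterministic"),
                                inoculum, params = NULL, law = NULL,
                                horizon, grid_step_min = 2, n_reps = 1,
                                stochastic_cap = 500, seed = NULL,
                                initial_phase = "uniform") {
  growth <- match.arg(growth)
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  grid <- seq(0, horizon, by = grid_step_min / 60)
  if (length(grid) < 2) stop("time grid is empty; decrease `grid_step_min`", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  ks <- draw_inocula(inoculum, n_reps)
  if (growth == "age") {
    stopifnot(inherits(law, "division_time_law"))
    mean_h <- law$mean_division_time / 60
    rate <- 60 * malthusian_rate(law)  # per hour
  } else {
    rate <- as_growth_params(params)$mu
  }
  one <- function(r) {
    k <- ks[r]
    if (growth == "deterministic") {
      ab <- k * exp(rate * grid)
    } else {
      ev <- if (growth == "sbp") {
        sbp_event_times(rate, k, stochastic_cap)
      } else {
        bh_events_cpp(as.integer(k), stochastic_cap, law$stages, mean_h,
                      initial_phase, mean_h)
      }
      ab <- k + findInterval(grid, ev)
      n_cap <- k + length(ev)
      if (length(ev) && n_cap >= stochastic_cap) {
        t_cap <- ev[length(ev)]
        over <- grid > t_cap
        ab[over] <- n_cap * exp(rate * (grid[over] - t_cap))
      }
    }
    tibble::tibble(replicate = r, inoculum = k, time_hours = grid, abundance = ab)
  }
  out <- dplyr::bind_rows(lapply(seq_len(n_reps), one))
  attr(out, "model") <- growth
  attr(out, "seed") <- seed
  out
}

#' Temporal variance accumulated by a stochastic-then-deterministic process
#'
#' A population grows as a simple birth process until `t_switch`, then
#' deterministically. To leading order in \eqn{1/n_0} the temporal variance
#' of the first-passage time at a distant threshold is
#' \deqn{\sigma_t^2(t_s) = \frac{1 - e^{-\mu t_s}}{\mu^2 n_0},}
#' reaching half of its asymptotic value \eqn{1/(\mu^2 n_0)} after a single
#' division time \eqn{\ln 2/\mu}: temporal variation accumulates while
#' populations are still small.
#'
#' @param params [growth_params()] or rate, 1/hour.
#' @param n0 Inoculum size.
#' @param t_switch Time(s) at which growth becomes deterministic, hours.
#' @return Variance in hours^2, same length as `t_switch`.
#' @export
two_step_variance <- function(params, n0, t_switch) {
  mu <- as_growth_params(params)$mu
  if (any(t_switch < 0)) stop("`t_switch` must be non-negative", call. = FALSE)
  -expm1(-mu * t_switch) / (mu^2 * n0)
}

#' Sample first-passage times of the two-step growth process
#'
#' Growth follows the simple birth process until `t_switch` — the abundance
#' \eqn{N(t_s)} is drawn from the exact Yule marginal (a shifted negative
#' binomial) — then becomes deterministic and exponential, so the FPT is
#' \eqn{T = \ln[\Omega/N(t_s)]/\mu}. Assumes the threshold is far above any
#' abundance reached during the stochastic phase (warned otherwise).
#'
#' @inheritParams two_step_variance
#' @param omega Threshold abundance.
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @return An `fpt_sample` tibble.
#' @export
sample_two_step_fpt <- function(params, n0, t_switch, omega, n_reps, seed = NULL) {
  mu <- as_growth_params(params)$mu
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (omega < 20 * n0 * exp(mu * t_switch)) {
    warning("threshold is not far above the expected abundance at t_switch; ",
            "the deterministic-tail approximation may be poor", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n_t <- n0 + stats::rnbinom(n_reps, size = n0, prob = exp(-mu * t_switch))
  times <- log(omega / n_t) / mu
  new_fpt_sample(times, rep.int(n0, n_reps), model = "two-step",
                 threshold = omega, seed = seed)
}
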