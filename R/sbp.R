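#' Abundance distribution of the simple birth process
#'
#' Probability that a population founded by `n0` individuals, each dividing
#' independently at rate \eqn{\mu}, consists of exactly `n` individuals at
#' time `t`:
#' \deqn{P_t(n \mid n_0) = \binom{n-1}{n_0-1} e^{-\mu n_0 t}
#'       (1 - e^{-\mu t})^{n - n_0}, \quad n \ge n_0.}
#' The binomial coefficient is evaluated in log space so thresholds in the
#' hundreds or thousands do not overflow. Probability is exactly 0 for
#' `n < n0` (a pure birth process cannot shrink).
#'
#' @param params [growth_params()] or a rate in 1/hour.
#' @param n0 Inoculum size, integer >= 1.
#' @param t Time, hours (>= 0). Vectorized over `t` or `n` (one at a time).
#' @param n Population size at which to evaluate the probability.
#' @param log If `TRUE` return log probability.
#' @return Probability (or log probability), same length as `t`/`n`.
#' @export
abundance_pmf <- function(params, n0, t, n, log = FALSE) {
  mu <- as_growth_params(params)$mu
  if (any(n0 < 1) || any(n0 != floor(n0))) stop("`n0` must be integer >= 1", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  k <- max(length(t), length(n))
  t <- rep_len(t, k); n <- rep_len(n, k)
  out <- numeric(k)
  below <- n < n0 | n != floor(n)
  out[below] <- if (log) -Inf else 0
  idx <- which(!below)
  if (length(idx)) {
    ti <- t[idx]; ni <- n[idx]
    # log P = lchoose(n-1, n0-1) - mu*n0*t + (n - n0) * log(1 - e^{-mu t})
    lq <- ifelse(ni == n0, 0, (ni - n0) * log(-expm1(-mu * ti)))
    lp <- lchoose(ni - 1, n0 - 1) - mu * n0 * ti + lq
    out[idx] <- if (log) lp else exp(lp)
  }
  out
}

#' Mean and variance of simple-birth-process abundance
#'
#' The abundance of a Yule population grows exponentially in expectation,
#' with mean \eqn{n_0 e^{\mu t}} and variance
#' \eqn{n_0 e^{\mu t}(e^{\mu t} - 1)}.
#'
#' @inheritParams abundance_pmf
#' @return A tibble with columns `t`, `mean`, `variance`.
#' @export
abundance_moments <- function(params, n0, t) {
  mu <- as_growth_params(params)$mu
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (any(n0 < 1)) stop("`n0` must be >= 1", call. = FALSE)
  g <- exp(mu * t)
  tibble::tibble(t = t, mean = n0 * g, variance = n0 * g * (g - 1))
}

#' Reaction probability: P(population has reached the threshold by time t)
#'
#' The probability that by time `t` the population size is at least
#' \eqn{\Omega}, i.e. one minus the abundance mass on \eqn{n_0, \ldots,
#' \Omega - 1}. Because abundance trajectories of a pure birth process are
#' monotone, this equals the cumulative distribution function of the
#' first-passage time at \eqn{\Omega}. Computed as a regularized incomplete
#' beta function (the tail of the shifted negative-binomial abundance law) for
#' numerical stability at large \eqn{\Omega}.
#'
#' @param params [growth_params()] or rate, 1/hour.
#' @param problem A [passage_problem()], or an inoculum size if `omega` given.
#' @param t Time(s), hours.
#' @param omega Optional threshold when `problem` is given as `n0`.
#' @return Probability, same length as `t`.
#' @export
reaction_probability <- function(params, problem, t, omega = NULL) {
  mu <- as_growth_params(params)$mu
  pr <- as_passage_problem(problem, omega)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  # N(t) - n0 is negative binomial(size n0, prob e^{-mu t});
  # P(N >= omega) = pbeta(1 - e^{-mu t}; omega - n0, n0)
  stats::pbeta(-expm1(-mu * t), pr$omega - pr$n0, pr$n0)
}

#' First-passage-time density at a population threshold
#'
#' Density of the time at which a Yule population founded by `n0` individuals
#' first reaches \eqn{\Omega} individuals:
#' \deqn{P^{FP}_\Omega(t \mid n_0) = \mu(\Omega - n_0)\binom{\Omega-1}{n_0-1}
#'       e^{-\mu n_0 t}(1 - e^{-\mu t})^{\Omega - n_0 - 1}.}
#' Evaluated via log-gamma arithmetic; integrates to 1 over \eqn{[0,\infty)}.
#'
#' @inheritParams reaction_probability
#' @return Density (1/hour), same length as `t`.
#' @export
fpt_density <- function(params, problem, t, omega = NULL) {
  mu <- as_growth_params(params)$mu
  pr <- as_passage_problem(problem, omega)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  n0 <- pr$n0; om <- pr$omega
  lc <- log(mu) + log(om - n0) + lchoose(om - 1, n0 - 1)
  lq <- if (om - n0 == 1) rep(0, length(t)) else (om - n0 - 1) * log(-expm1(-mu * t))
  out <- exp(lc - mu * n0 * t + lq)
  out[t == 0 & om - n0 > 1] <- 0
  out
}

# partial sums sum_{n=n0}^{omega-1} 1/n and 1/n^2; polygamma differences,
# direct summation below 1e3 for transparency
harmonic_partial <- function(n0, omega, power = 1) {
  if (omega - n0 < 1000) {
    n <- seq(n0, omega - 1)
    sum(1 / n^power)
  } else if (power == 1) {
    digamma(omega) - digamma(n0)
  } else {
    trigamma(n0) - trigamma(omega)
  }
}

#' Mean, variance and TSD of the first-passage time (simple birth process)
#'
#' Waiting times between successive divisions of a size-`n` Yule population
#' are independent exponentials with rate \eqn{\mu n}, so
#' \deqn{\langle t\rangle = \frac{1}{\mu}\sum_{n=n_0}^{\Omega-1}\frac{1}{n},
#' \qquad \sigma_t^2 = \frac{1}{\mu^2}\sum_{n=n_0}^{\Omega-1}\frac{1}{n^2}.}
#' Partial sums are evaluated as digamma/trigamma differences, so thresholds
#' up to \eqn{10^8} and beyond are exact and O(1); below \eqn{\Omega = 10^3}
#' the sums are accumulated directly.
#'
#' @inheritParams reaction_probability
#' @return One-row tibble: `mean` (hours), `variance` (hours^2), `tsd` (hours).
#' @examples
#' fpt_moments(1, passage_problem(1, 4))  # mean 11/6, variance 49/36
#' @export
fpt_moments <- function(params, problem, omega = NULL) {
  mu <- as_growth_params(params)$mu
  pr <- as_passage_problem(problem, omega)
  m <- harmonic_partial(pr$n0, pr$omega, 1) / mu
  v <- harmonic_partial(pr$n0, pr$omega, 2) / mu^2
  tibble::tibble(mean = m, variance = v, tsd = sqrt(v))
}

#' Large-threshold asymptotic temporal standard deviation
#'
#' For thresholds far above the inoculum the TSD of the simple birth process
#' asymptotes to \eqn{1/(\mu\sqrt{n_0})}; the same power law holds for
#' Poisson-distributed inocula with deterministic growth.
#'
#' @param params [growth_params()] or rate, 1/hour.
#' @param n0 Inoculum size(s) >= 1.
#' @return TSD in hours, same length as `n0`.
#' @export
tsd_asymptotic <- function(params, n0) {
  mu <- as_growth_params(params)$mu
  if (any(n0 < 1)) stop("`n0` must be >= 1", call. = FALSE)
  1 / (mu * sqrt(n0))
}
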