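#' Growth parameters for exponential population growth
#'
#' Bundles the per-capita division rate \eqn{\mu} (per hour). For a population
#' of size \eqn{n} under the simple birth process the total division rate is
#' \eqn{B_n = \mu n}.
#'
#' @param mu Per-capita division rate, 1/hour. Must be strictly positive.
#' @return An object of class `growth_params`.
#' @examples
#' gp <- growth_params(1.66)
#' division_time(gp)  # hours
#' @export
growth_params <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a single positive finite number (per hour)", call. = FALSE)
  }
  structure(list(mu = as.numeric(mu)), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params> mu = %g /hr (division time %.3g h)\n",
              x$mu, division_time(x)))
  invisible(x)
}

#' Division time ln(2)/mu
#'
#' @param params A [growth_params()] object or a positive rate (per hour).
#' @return Division time in hours.
#' @export
division_time <- function(params) {
  mu <- if (inherits(params, "growth_params")) params$mu else params
  stopifnot(is.numeric(mu), mu > 0)
  log(2) / mu
}

#' First-passage problem: inoculum and threshold
#'
#' Defines the question "when does a population founded by `n0` individuals
#' first reach `omega` individuals?".
#'
#' @param n0 Inoculum size, integer, at least 1.
#' @param omega Threshold population size, integer, strictly greater than `n0`.
#' @return An object of class `passage_problem`.
#' @export
passage_problem <- function(n0, omega) {
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1 || n0 != floor(n0)) {
    stop("`n0` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega != floor(omega) || omega <= n0) {
    stop("`omega` must be a single integer > n0", call. = FALSE)
  }
  structure(list(n0 = as.numeric(n0), omega = as.numeric(omega)),
            class = "passage_problem")
}

#' @export
print.passage_problem <- function(x, ...) {
  cat(sprintf("<passage_problem> n0 = %g -> omega = %g\n", x$n0, x$omega))
  invisible(x)
}

#' Division-time law for age-structured growth
#'
#' Either exponential division times (the simple birth process limit) or a
#' k-stage law: progression through `stages` Poisson stages gives an Erlang
#' division-time distribution, equivalently a chi-squared distribution with
#' `2 * stages` degrees of freedom linearly rescaled to the stated mean. Its
#' coefficient of variation is \eqn{1/\sqrt{k}}, so 20 stages gives CV
#' of about 22% and one stage gives CV 100%.
#'
#' @param family `"exponential"` or `"stage-structured"`.
#' @param stages Number of stages k (integer >= 1); forced to 1 for the
#'   exponential family.
#' @param mean_division_time Mean division time, minutes.
#' @return An object of class `division_time_law`.
#' @examples
#' law <- division_time_law("stage-structured", stages = 20,
#'                          mean_division_time = 25)
#' law_cv(law)  # 1/sqrt(20), about 0.224
#' @export
division_time_law <- function(family = c("stage-structured", "exponential"),
                              stages = 20, mean_division_time = 25) {
  family <- match.arg(family)
  if (family == "exponential") stages <- 1L
  if (!is.numeric(stages) || length(stages) != 1L || stages < 1 ||
      stages != floor(stages)) {
    stop("`stages` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(mean_division_time) || mean_division_time <= 0) {
    stop("`mean_division_time` must be positive (minutes)", call. = FALSE)
  }
  if (stages == 1L) family <- "exponential"
  structure(list(family = family, stages = as.integer(stages),
                 mean_division_time = as.numeric(mean_division_time)),
            class = "division_time_law")
}

#' Coefficient of variation of a division-time law
#' @param law A [division_time_law()].
#' @return CV as a fraction (1/sqrt(stages)).
#' @export
law_cv <- function(law) {
  stopifnot(inherits(law, "division_time_law"))
  1 / sqrt(law$stages)
}

#' @export
print.division_time_law <- function(x, ...) {
  cat(sprintf("<division_time_law> %s, k = %d stages, mean %.3g min (CV %.1f%%)\n",
              x$family, x$stages, x$mean_division_time, 100 * law_cv(x)))
  invisible(x)
}

#' Inoculum law: exact or zero-truncated Poisson
#'
#' @param kind `"exact"` (every replicate starts with `value` individuals) or
#'   `"poisson"` (inoculum drawn from a zero-truncated Poisson with shape
#'   parameter `value`).
#' @param value Exact inoculum size (integer >= 1) or Poisson shape (> 0).
#' @return An object of class `inoculum_law`.
#' @export
inoculum_law <- function(kind = c("exact", "poisson"), value = 1) {
  kind <- match.arg(kind)
  if (kind == "exact") {
    if (!is.numeric(value) || value < 1 || value != floor(value)) {
      stop("exact inoculum `value` must be an integer >= 1", call. = FALSE)
    }
  } else if (!is.numeric(value) || value <= 0) {
    stop("Poisson shape `value` must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, value = as.numeric(value)), class = "inoculum_law")
}

#' @export
print.inoculum_law <- function(x, ...) {
  lab <- if (x$kind == "exact") sprintf("exact n0 = %g", x$value)
         else sprintf("zero-truncated Poisson, shape = %g (zt mean %.3g)",
                      x$value, ztpois_mean(x$value))
  cat("<inoculum_law> ", lab, "\n", sep = "")
  invisible(x)
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) x else growth_params(x)
}

as_passage_problem <- function(n0, omega) {
  if (inherits(n0, "passage_problem")) n0 else passage_problem(n0, omega)
}
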