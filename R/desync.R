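#' Poles of the age-structured renewal equation
#'
#' A deterministic age-structured population with division-time density
#' \eqn{f} grows according to the renewal equation, whose Laplace-space
#' characteristic equation is \eqn{2\hat f(s) = 1}. For a k-stage Erlang law
#' with mean \eqn{\tau} (stage scale \eqn{\theta = \tau/k}),
#' \eqn{\hat f(s) = (1 + \theta s)^{-k}} and the roots are
#' \deqn{s_j = \frac{2^{1/k} e^{2\pi i j / k} - 1}{\theta}, \quad
#'       j = 0, \pm 1, \ldots}
#' The dominant real root \eqn{s_0} is the Malthusian (asymptotic exponential)
#' growth rate; the leading complex pair \eqn{s_{\pm 1}} governs the decaying
#' growth-rate oscillations of an initially synchronized population. The
#' relative oscillation amplitude shrinks by
#' \eqn{\exp[(\mathrm{Re}\,s_1 - s_0)\tau]} per division cycle.
#'
#' @param law A [division_time_law()] (exponential or stage-structured; these
#'   are the laws with rational Laplace transforms).
#' @return An object of class `pole_set`: a list with `malthusian_rate`
#'   (1/minute), `subdominant_pole` (complex, 1/minute; `NA` for the 1-stage
#'   law, which has no oscillatory pair), `decay_per_cycle`,
#'   `oscillation_period` (minutes) and the law.
#' @examples
#' renewal_poles(division_time_law("stage-structured", 20, 25))
#' @export
renewal_poles <- function(law) {
  if (!inherits(law, "division_time_law")) {
    stop("`law` must be a division_time_law (rational Laplace transform)", call. = FALSE)
  }
  k <- law$stages
  theta <- law$mean_division_time / k   # minutes
  s0 <- (2^(1 / k) - 1) / theta
  if (k == 1) {
    s1 <- NA_complex_
    dpc <- NA_real_
    period <- NA_real_
  } else {
    s1 <- (2^(1 / k) * exp(2i * pi / k) - 1) / theta
    dpc <- exp((Re(s1) - s0) * law$mean_division_time)
    period <- 2 * pi / Im(s1)
  }
  structure(list(malthusian_rate = s0, subdominant_pole = s1,
                 decay_per_cycle = dpc, oscillation_period = period,
                 law = law),
            class = "pole_set")
}

#' @export
print.pole_set <- function(x, ...) {
  cat(sprintf("<pole_set> Malthusian rate %.5g /min (%.4g /hr)\n",
              x$malthusian_rate, 60 * x$malthusian_rate))
  if (is.na(x$decay_per_cycle)) {
    cat("  1-stage (exponential) law: no oscillatory pole\n")
  } else {
    cat(sprintf("  subdominant pole %.5g %+.5gi /min; oscillation period %.4g min\n",
                Re(x$subdominant_pole), Im(x$subdominant_pole), x$oscillation_period))
    cat(sprintf("  amplitude decay per division cycle: %.4g\n", x$decay_per_cycle))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy pole_set
#' @export
tidy.pole_set <- function(x, ...) {
  tibble::tibble(
    stages = x$law$stages,
    mean_division_min = x$law$mean_division_time,
    malthusian_rate_per_min = x$malthusian_rate,
    re_s1_per_min = Re(x$subdominant_pole),
    im_s1_per_min = Im(x$subdominant_pole),
    decay_per_cycle = x$decay_per_cycle,
    oscillation_period_min = x$oscillation_period
  )
}

#' Malthusian growth rate of a division-time law
#'
#' Dominant real root of the renewal characteristic equation: the asymptotic
#' per-capita exponential growth rate of an age-structured population. For
#' finite k this exceeds \eqn{\ln 2/\tau} (it is \eqn{k(2^{1/k}-1)/\tau}),
#' decreasing to \eqn{\ln 2/\tau} as \eqn{k \to \infty}.
#'
#' @param law A [division_time_law()].
#' @return Rate in 1/minute.
#' @export
malthusian_rate <- function(law) {
  renewal_poles(law)$malthusian_rate
}

#' Division cycles until growth-rate oscillations fall below a fraction
#'
#' The relative oscillation amplitude after c division cycles is
#' `decay_per_cycle^c`; this returns the number of cycles for the amplitude
#' to fall to `amplitude_fraction` of its initial value,
#' \eqn{\ln(f)/\ln(\mathrm{decay\_per\_cycle})}. Operationalizes "growth has
#' become effectively exponential" as amplitude below the given fraction
#' (default 5%).
#'
#' @param poles A `pole_set` from [renewal_poles()] (or a
#'   [division_time_law()], converted on the fly).
#' @param amplitude_fraction Fraction in (0, 1); default 0.05.
#' @return Number of division cycles (0 with attribute
#'   `no_oscillation = TRUE` for the exponential law, which has no
#'   oscillatory pole to decay).
#' @export
cycles_to_asymptote <- function(poles, amplitude_fraction = 0.05) {
  if (inherits(poles, "division_time_law")) poles <- renewal_poles(poles)
  stopifnot(inherits(poles, "pole_set"))
  if (amplitude_fraction <= 0 || amplitude_fraction >= 1) {
    stop("`amplitude_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (is.na(poles$decay_per_cycle)) {
    return(structure(0, no_oscillation = TRUE))
  }
  log(amplitude_fraction) / log(poles$decay_per_cycle)
}

#' Time-domain renewal integration of the per-capita division rate
#'
#' Integrates the renewal equation
#' \eqn{b(t) = n_0 f(t) + 2\int_0^t f(u)\, b(t-u)\, du}
#' for the division-event rate \eqn{b} of a population founded by a
#' synchronized cohort of newborns, on a regular time grid (trapezoid-free
#' left-Riemann convolution; the grid step should be well below the stage
#' scale). The per-capita division rate \eqn{b(t)/N(t)}, with
#' \eqn{N(t) = n_0 + \int_0^t b}, oscillates about the Malthusian rate with
#' an envelope decaying at \eqn{\mathrm{Re}\,s_1 - s_0}.
#'
#' @param law A [division_time_law()].
#' @param dt Grid step, minutes.
#' @param horizon Integration horizon, minutes.
#' @param n0 Founding cohort size (scales out of per-capita quantities).
#' @return A tibble: `time_min`, `birth_rate`, `population`,
#'   `percap_rate` (1/minute).
#' @export
renewal_rate_curve <- function(law, dt = 0.02, horizon = 160, n0 = 1) {
  stopifnot(inherits(law, "division_time_law"))
  tt <- seq(0, horizon, by = dt)
  m <- length(tt)
  f <- stats::dgamma(tt, shape = law$stages, scale = law$mean_division_time / law$stages)
  b <- numeric(m)
  b[1] <- n0 * f[1]
  for (i in 2:m) {
    # convolution sum_{j=1}^{i-1} f[j+1] * b[i-j]  (u > 0 lags)
    conv <- sum(f[2:i] * b[(i - 1):1])
    b[i] <- n0 * f[i] + 2 * dt * conv
  }
  pop <- n0 + dt * cumsum(b)
  tibble::tibble(time_min = tt, birth_rate = b, population = pop,
                 percap_rate = b / pop)
}

#' Measure the decay rate of growth-rate oscillations from a renewal curve
#'
#' Locates successive local extrema of the per-capita division rate around
#' the Malthusian rate and fits a line to the log of their absolute
#' deviations, giving the empirical envelope decay rate (1/minute), to be
#' compared with \eqn{\mathrm{Re}\,s_1 - s_0} from [renewal_poles()].
#'
#' @param curve Output of [renewal_rate_curve()].
#' @param law The [division_time_law()] used to generate it.
#' @param t_min Discard extrema before this time (minutes); defaults to one
#'   mean division time, past the initial transient.
#' @param t_max Discard extrema after this time (minutes); defaults to six
#'   mean division times, before amplitudes approach the integration's
#'   numerical floor.
#' @return A list: `decay_rate` (1/minute, negative), `n_peaks`, and the
#'   peak table.
#' @export
oscillation_decay_rate <- function(curve, law, t_min = NULL, t_max = NULL) {
  s0 <- malthusian_rate(law)
  if (is.null(t_min)) t_min <- law$mean_division_time
  if (is.null(t_max)) t_max <- 6 * law$mean_division_time
  dev <- curve$percap_rate - s0
  a <- abs(dev)
  n <- length(a)
  is_peak <- c(FALSE, a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n], FALSE)
  keep <- is_peak & curve$time_min > t_min & curve$time_min < t_max & a > 1e-12
  peaks <- tibble::tibble(time_min = curve$time_min[keep], amplitude = a[keep])
  if (nrow(peaks) < 3) stop("too few oscillation peaks; extend the horizon", call. = FALSE)
  fit <- stats::lm(log(amplitude) ~ time_min, data = peaks)
  list(decay_rate = unname(stats::coef(fit)[2]), n_peaks = nrow(peaks),
       peaks = peaks)
}
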