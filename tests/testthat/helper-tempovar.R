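# shared helpers for statistical comparisons on simulated samples

# standard error of a sample mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))

# standard error of a sample variance (moment-based, no normality assumption)
se_var <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  sqrt((m4 - stats::var(x)^2 * (n - 3) / (n - 1)) / n)
}

# standard error of a sample standard deviation (delta method from se_var)
se_sd <- function(x) se_var(x) / (2 * stats::sd(x))

# long-format trajectory tibble from a closed-form signal
make_trajectory <- function(f, horizon_hours, step_min, replicate = 1) {
  tt <- seq(0, horizon_hours, by = step_min / 60)
  tibble::tibble(replicate = replicate, time_hours = tt, abundance = f(tt))
}
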