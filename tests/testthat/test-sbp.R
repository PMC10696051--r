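test_that("abundance pmf matches the geometric/negative-binomial law", {
  # initial condition and impossibility of shrinking
  expect_equal(abundance_pmf(1, 1, 0, 1), 1)
  expect_identical(abundance_pmf(1, 3, 5, 2), 0)
  # n0 = 1 reduces to a geometric law: e^{-mu t}(1 - e^{-mu t})^{n-1}
  expect_equal(abundance_pmf(1, 1, log(2), 3), 0.125)
  # independent route: abundance minus inoculum is negative binomial with
  # size n0 and success probability e^{-mu t}
  mu <- 0.7; n0 <- 4; t <- 1.3
  n <- n0:60
  expect_equal(abundance_pmf(mu, n0, t, n),
               dnbinom(n - n0, size = n0, prob = exp(-mu * t)),
               tolerance = 1e-12)
  # normalization over a support holding all but ~1e-12 of the mass
  n_all <- n0:qnbinom(1e-13, n0, exp(-mu * t), lower.tail = FALSE)
  expect_equal(sum(abundance_pmf(mu, n0, t, n_all)), 1, tolerance = 1e-10)
  expect_error(abundance_pmf(1, 0, 1, 1), "n0")
  expect_error(abundance_pmf(1, 1, -1, 1), "non-negative")
})

test_that("abundance moments grow exponentially and match simulation", {
  expect_equal(abundance_moments(1, 2, 0)$mean, 2)
  expect_equal(abundance_moments(1, 2, 0)$variance, 0)
  m <- abundance_moments(1, 2, log(2))
  expect_equal(m$mean, 4)
  expect_equal(m$variance, 4)
  # Monte-Carlo oracle via gridded trajectories
  tr <- sample_trajectories("sbp", inoculum_law("exact", 5), params = 0.5,
                            horizon = 2, grid_step_min = 60, n_reps = 10000,
                            stochastic_cap = 1000, seed = 71)
  at2 <- tr$abundance[tr$time_hours == 2]
  th <- abundance_moments(0.5, 5, 2)
  expect_lt(abs(mean(at2) - th$mean), 3 * se_mean(at2))
  expect_lt(abs(var(at2) - th$variance), 3 * se_var(at2))
})

test_that("reaction probability is the first-passage CDF", {
  pr <- passage_problem(1, 5)
  expect_equal(reaction_probability(1, pr, 0), 0)
  # omega = n0 + 1 is a single exponential waiting time
  t <- c(0.3, 1, 2.5)
  expect_equal(reaction_probability(1, passage_problem(1, 2), t), 1 - exp(-t))
  # equals the integral of the first-passage density
  num <- integrate(function(u) fpt_density(1, pr, u), 0, 2,
                   rel.tol = 1e-10)$value
  expect_equal(reaction_probability(1, pr, 2), num, tolerance = 1e-8)
  # equals one minus the abundance mass below the threshold (independent route)
  expect_equal(reaction_probability(1, pr, 1.7),
               1 - sum(abundance_pmf(1, 1, 1.7, 1:4)), tolerance = 1e-12)
  # non-decreasing, saturating at 1
  grid <- seq(0, 12, by = 0.1)
  rp <- reaction_probability(1, pr, grid)
  expect_true(all(diff(rp) >= 0))
  expect_equal(rp[length(rp)], 1, tolerance = 1e-3)
  # derivative matches the density pointwise
  h <- 1e-5
  mid <- c(0.5, 1, 2)
  dnum <- (reaction_probability(1, pr, mid + h) -
             reaction_probability(1, pr, mid - h)) / (2 * h)
  expect_equal(dnum, fpt_density(1, pr, mid), tolerance = 1e-6)
})

test_that("first-passage density is normalized with the expected mode", {
  # adjacent threshold reduces to Exp(mu * n0)
  t <- c(0.1, 0.5, 2)
  expect_equal(fpt_density(1, passage_problem(3, 4), t), 3 * exp(-3 * t))
  pr <- passage_problem(1, 5)
  expect_equal(integrate(function(u) fpt_density(1, pr, u), 0, Inf,
                         rel.tol = 1e-12)$value, 1, tolerance = 1e-8)
  # mode at ln(omega - 1)/mu for n0 = 1
  pr10 <- passage_problem(1, 10)
  opt <- optimize(function(u) fpt_density(1, pr10, u), c(0.1, 10),
                  maximum = TRUE)
  expect_equal(opt$maximum, log(9), tolerance = 1e-5)
  grid <- seq(0.01, 10, by = 0.01)
  expect_equal(grid[which.max(fpt_density(1, pr10, grid))], log(9),
               tolerance = 0.01)
})

test_that("first-passage moments are partial harmonic sums", {
  m <- fpt_moments(1, passage_problem(1, 2))
  expect_equal(unlist(m), c(mean = 1, variance = 1, tsd = 1))
  m4 <- fpt_moments(1, passage_problem(1, 4))
  expect_equal(m4$mean, 1 + 1 / 2 + 1 / 3)
  expect_equal(m4$variance, 1 + 1 / 4 + 1 / 9)
  expect_equal(m4$tsd, sqrt(1 + 1 / 4 + 1 / 9))
  # rates scale out
  expect_equal(fpt_moments(2, passage_problem(3, 50))$mean,
               fpt_moments(1, passage_problem(3, 50))$mean / 2)
  # polygamma evaluation agrees with direct summation across the switchover
  for (om in c(995, 1000, 1005, 20000)) {
    n <- seq(7, om - 1)
    expect_equal(fpt_moments(1, passage_problem(7, om))$mean, sum(1 / n),
                 tolerance = 1e-12)
    expect_equal(fpt_moments(1, passage_problem(7, om))$variance,
                 sum(1 / n^2), tolerance = 1e-12)
  }
  # Basel limit of the variance for n0 = 1
  expect_equal(fpt_moments(1, passage_problem(1, 1e7))$variance, pi^2 / 6,
               tolerance = 1e-6)
})

test_that("TSD obeys the large-threshold asymptote and monotonicity", {
  expect_equal(tsd_asymptotic(2, 4), 0.25)
  expect_equal(tsd_asymptotic(1, 1), 1)
  expect_error(tsd_asymptotic(1, 0), ">= 1")
  # exact TSD approaches 1/(mu sqrt(n0)) for omega >> n0 >> 1
  r <- fpt_moments(1, passage_problem(100, 1e6))$tsd / tsd_asymptotic(1, 100)
  expect_lt(abs(r - 1), 0.01)
  # strictly decreasing in n0 at fixed omega
  tsds <- vapply(c(1, 2, 5, 10, 20),
                 function(k) fpt_moments(1, passage_problem(k, 500))$tsd,
                 numeric(1))
  expect_true(all(diff(tsds) < 0))
  # non-decreasing in omega; converged to the asymptote by omega ~ 50
  by_om <- vapply(c(5, 10, 50, 200, 1e6),
                  function(om) fpt_moments(1, passage_problem(1, om))$tsd,
                  numeric(1))
  expect_true(all(diff(by_om) >= 0))
  expect_gt(by_om[3] / by_om[5], 0.99)
})

test_that("first-passage moments agree with a Monte-Carlo oracle", {
  s <- sample_sbp_fpt(1, inoculum_law("exact", 2), 20, 1e5, seed = 9)
  th <- fpt_moments(1, passage_problem(2, 20))
  expect_lt(abs(mean(s$fpt_hours) - th$mean), 4 * se_mean(s$fpt_hours))
  expect_lt(abs(var(s$fpt_hours) - th$variance), 4 * se_var(s$fpt_hours))
})
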