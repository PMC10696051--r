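# deterministic, noiseless plate with exact inocula: the sharpest test bed
det_config <- function(...) {
  fixture_config(model = "deterministic", mu = 1.8,
                 inocula = c(a = 5), inoculum_kind = "exact",
                 wells_per_group = 6, n_blank = 2, noise_sd = 0,
                 baseline = 0.11, carrying_od = 4.3, seed = 2)
}

test_that("background subtraction recovers the plate baseline", {
  fx <- generate_plate(fixture_config(model = "deterministic", mu = 1.8,
                                      inocula = c(a = 5), inoculum_kind = "exact",
                                      wells_per_group = 20, n_blank = 4,
                                      noise_sd = 0.001, baseline = 0.110,
                                      seed = 3))
  run <- subtract_background(fx$run)
  expect_lt(abs(run$background - 0.110), 0.001 / sqrt(24) * 4)
  # corrected blanks fluctuate around 0 with the configured noise
  blanks <- run$od[run$od$well %in% run$meta$well[run$meta$blank], ]
  # corrected blanks share the background-estimate error, noise/sqrt(wells)
  expect_lt(abs(mean(blanks$od)), 4 * 0.001 / sqrt(24))
  expect_lt(abs(sd(blanks$od) - 0.001), 0.001 * 0.2)
  # idempotent: corrected signal always derives from the raw readings
  run2 <- subtract_background(run)
  expect_identical(run2$od$od, run$od$od)
  # all-constant wells at time 0 start at 0 after correction
  fx0 <- generate_plate(det_config())
  run0 <- subtract_background(fx0$run)
  at0 <- run0$od$od[run0$od$time_min == 0]
  expect_lt(max(abs(at0)), 1e-6)
})

test_that("QC flags condensation-like wells at the raw-OD cutoff", {
  fx <- generate_plate(fixture_config(model = "deterministic", mu = 1.8,
                                      inocula = c(a = 5, b = 5), inoculum_kind = "exact",
                                      wells_per_group = 42, n_blank = 6,
                                      noise_sd = 0, seed = 4))
  run <- fx$run
  # plant: one well just above, one just below the cutoff at the 1-h reading
  i60 <- run$od$time_min == 60
  run$od$od_raw[i60 & run$od$well == "W01"] <- 0.130
  run$od$od_raw[i60 & run$od$well == "W02"] <- 0.120
  run$od$od_raw[i60 & run$od$well %in% c("W05", "W09")] <- 0.2
  run <- apply_qc_filters(run, manual_exclusions = "W11")
  expect_setequal(run$qc$well, c("W01", "W05", "W09", "W11"))
  qs <- attr(run, "qc_summary")
  expect_equal(qs$n_wells, 84)
  expect_equal(qs$n_flagged, 4)
  expect_equal(qs$fraction_flagged, 4 / 84)
  # 3 automatically planted bad wells out of 84
  run3 <- apply_qc_filters(fx$run)
  expect_equal(attr(run3, "qc_summary")$n_flagged, 0)
})

test_that("log-window growth rate recovers exact exponential growth", {
  fx <- generate_plate(det_config())
  run <- subtract_background(fx$run)
  fit <- log_window_growth_rate(run, od_threshold = 0.03, window = 30)
  expect_lt(max(abs(tidy(fit)$rate_per_hr - 1.8)), 5e-6)
  expect_equal(glance(fit)$pooled_rate_per_hr, 1.8, tolerance = 1e-5)
})

test_that("pooled growth rate is robust to measurement noise", {
  fx <- generate_plate(fixture_config(model = "deterministic", mu = 2.0,
                                      inocula = c(a = 5, b = 20), inoculum_kind = "exact",
                                      wells_per_group = 12, n_blank = 2,
                                      noise_sd = 0.001, carrying_od = 4.3,
                                      seed = 6))
  run <- subtract_background(fx$run)
  fit <- log_window_growth_rate(run)
  expect_lt(abs(fit$pooled_rate - 2.0) / 2.0, 0.02)
})

test_that("growth rates fall when evaluated into the saturating regime", {
  cfg <- fixture_config(model = "deterministic", mu = 1.8,
                        inocula = c(a = 5), inoculum_kind = "exact",
                        wells_per_group = 4, n_blank = 2, noise_sd = 0,
                        carrying_od = 0.1, seed = 7)
  run <- subtract_background(generate_plate(cfg)$run)
  r_low <- log_window_growth_rate(run, od_threshold = 0.02)$pooled_rate
  r_high <- log_window_growth_rate(run, od_threshold = 0.05)$pooled_rate
  expect_gt(r_low, r_high)
  expect_equal(r_low, 1.8, tolerance = 1e-4)
})

test_that("TSD is flat across threshold OD for stochastic exponential growth", {
  fx <- generate_plate(fixture_config(model = "sbp", mu = 1.8,
                                      inocula = c(a = 5), wells_per_group = 40,
                                      n_blank = 4, noise_sd = 0.001, seed = 9))
  run <- apply_qc_filters(subtract_background(fx$run))
  tb <- suppressWarnings(tsd_vs_threshold(run, n_boot = 300, seed = 10))
  expect_true(all(tb$threshold >= 0.01 & tb$threshold <= 0.3))
  expect_lt(max(tb$tsd) / min(tb$tsd), 1.3)
  # measured TSD sits above the exact-inoculation SBP floor
  at03 <- tb$tsd[which.min(abs(tb$threshold - 0.03))]
  lower <- tsd_asymptotic(1.8, ztpois_mean(5))
  n <- tb$n_crossed[which.min(abs(tb$threshold - 0.03))]
  expect_gt(at03, lower - 3 * at03 / sqrt(2 * (n - 1)))
})

test_that("identical deterministic wells give zero TSD at all thresholds", {
  run <- subtract_background(generate_plate(det_config())$run)
  tb <- tsd_vs_threshold(run, thresholds = c(0.02, 0.05, 0.2), n_boot = 50)
  expect_lt(max(tb$tsd), 1e-8)
})

test_that("TSDs at different growth rates collapse in division-time units", {
  mk <- function(mu, seed) {
    cfg <- fixture_config(model = "sbp", mu = mu, inocula = c(a = 5),
                          inoculum_kind = "exact", wells_per_group = 30,
                          n_blank = 2, noise_sd = 0.001,
                          horizon_hours = 48, seed = seed)
    run <- subtract_background(generate_plate(cfg)$run)
    fs <- threshold_crossing_times(
      dplyr::mutate(plate_od(run), time_hours = time_min / 60),
      0.03, value_col = "od", replicate_col = "well")
    tsd_with_ci(fs, level = 0.95, n_boot = 500, seed = seed + 1)
  }
  slow <- mk(0.8, 21)
  fast <- mk(1.8, 22)
  slow_dt <- tsd_in_division_times(c(slow$ci_low, slow$ci_high), 0.8)
  fast_dt <- tsd_in_division_times(c(fast$ci_low, fast$ci_high), 1.8)
  # intervals in division-time units overlap
  expect_lt(max(slow_dt[1], fast_dt[1]), min(slow_dt[2], fast_dt[2]))
})

test_that("standard curve interpolates calibration points and guards range", {
  sc <- fit_standard_curve(c(0.03, 0.6), c(1.4e7, 2.8e8))
  expect_equal(od_to_cfu(sc, 0.03), 1.4e7)
  expect_equal(od_to_cfu(sc, 0.6), 2.8e8)
  expect_warning(od_to_cfu(sc, 0.7), "range")
  expect_equal(cfu_to_od(sc, od_to_cfu(sc, 0.2)), 0.2)
  withr::with_seed(23, {
    od <- runif(20, 0.01, 0.6)
    cfu <- 4.67e8 * od * (1 + rnorm(20, sd = 0.02))
    scn <- fit_standard_curve(od, cfu)
    expect_lt(abs(scn$slope - 4.67e8) / 4.67e8, 0.05)
  })
  expect_error(fit_standard_curve(c(0.1, 0.1), c(1, 2)), "constant")
})

test_that("lag-phase diagnostic is zero without lag and shifts with it", {
  sc <- fit_standard_curve(c(0.03, 0.6), c(1.4e7, 2.8e8))
  run0 <- subtract_background(generate_plate(det_config())$run)
  chk0 <- lag_phase_check(run0, sc, mu = 1.8, n0 = 5)
  # exact parameters: only grid-interpolation error remains
  expect_lt(abs(chk0$delta_min), 1.5)
  cfg_lag <- fixture_config(model = "deterministic", mu = 1.8,
                            inocula = c(a = 5), inoculum_kind = "exact",
                            wells_per_group = 6, n_blank = 2, noise_sd = 0,
                            carrying_od = 4.3, lag_min = 60, seed = 2)
  run_lag <- subtract_background(generate_plate(cfg_lag)$run)
  chk_lag <- lag_phase_check(run_lag, sc, mu = 1.8, n0 = 5)
  expect_equal(chk0$delta_min - chk_lag$delta_min, 60, tolerance = 0.5)
  # matched stochastic growth: mean observed crossing lags the deterministic
  # crossing of the mean trajectory, so delta <= 0 at zero lag
  fx <- generate_plate(fixture_config(model = "sbp", mu = 1.8,
                                      inocula = c(a = 2), inoculum_kind = "exact",
                                      wells_per_group = 40, n_blank = 2,
                                      noise_sd = 0, seed = 24))
  run_s <- subtract_background(fx$run)
  chk_s <- lag_phase_check(run_s, sc, mu = 1.8, n0 = 2)
  expect_lt(chk_s$delta_min, 0)
  expect_error(lag_phase_check(run0, sc, 1.8, 5, od_threshold = 0.005),
               "calibration")
})
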