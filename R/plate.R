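#' Build a plate run from OD readings and well metadata
#'
#' A plate run holds an OD600 well-by-time table in long form together with
#' per-well metadata (inoculum group, blank flag), the per-plate background
#' estimate and quality-control flags.
#'
#' @param od Either a wide data frame (first column time in minutes, one
#'   column per well) or a long data frame with columns `time_min`, `well`,
#'   `od`.
#' @param meta Data frame with columns `well`, `group` and logical `blank`.
#' @param metadata Optional named list (plate id, temperature, ...).
#' @return An object of class `plate_run`.
#' @export
plate_run <- function(od, meta, metadata = list()) {
  stopifnot(is.data.frame(od), is.data.frame(meta))
  if (all(c("time_min", "well", "od") %in% names(od))) {
    long <- tibble::as_tibble(od[c("time_min", "well", "od")])
  } else {
    names(od)[1] <- "time_min"
    long <- tidyr::pivot_longer(tibble::as_tibble(od), -"time_min",
                                names_to = "well", values_to = "od")
  }
  if (!all(c("well", "group") %in% names(meta))) {
    stop("`meta` needs columns `well` and `group`", call. = FALSE)
  }
  if (!"blank" %in% names(meta)) meta$blank <- FALSE
  missing_meta <- setdiff(unique(long$well), meta$well)
  if (length(missing_meta)) {
    stop("wells without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  tt <- sort(unique(long$time_min))
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  long <- dplyr::arrange(long, .data$well, .data$time_min)
  long$od_raw <- long$od
  structure(list(od = long,
                 meta = tibble::as_tibble(meta),
                 background = NA_real_,
                 qc = tibble::tibble(well = character(), reason = character()),
                 metadata = metadata),
            class = "plate_run")
}

#' Read a plate run from CSV files
#'
#' @param od_file CSV of OD readings, wide (first column time in minutes,
#'   remaining columns wells) or long (`time_min`, `well`, `od`).
#' @param meta_file CSV mapping `well` to `group` (and optional logical
#'   `blank`).
#' @param ... Passed to [plate_run()].
#' @return A `plate_run`.
#' @export
read_plate <- function(od_file, meta_file, ...) {
  od <- readr::read_csv(od_file, show_col_types = FALSE)
  meta <- readr::read_csv(meta_file, show_col_types = FALSE)
  plate_run(od, meta, ...)
}

#' @export
print.plate_run <- function(x, ...) {
  nt <- length(unique(x$od$time_min))
  cat(sprintf("<plate_run> %d wells x %d times (%.1f h); background %s; %d flagged\n",
              nrow(x$meta), nt, max(x$od$time_min) / 60,
              if (is.na(x$background)) "not subtracted" else sprintf("%.4f", x$background),
              nrow(x$qc)))
  invisible(x)
}

flagged_wells <- function(run) unique(run$qc$well)

active_od <- function(run) {
  keep <- run$meta$well[!run$meta$blank & !(run$meta$well %in% flagged_wells(run))]
  dplyr::filter(run$od, .data$well %in% keep)
}

well_groups <- function(run) {
  stats::setNames(run$meta$group, run$meta$well)
}

#' Long-format OD table of a plate run
#'
#' @param run A `plate_run`.
#' @param active Keep only retained growth wells (drop blanks and
#'   QC-flagged wells)?
#' @return A tibble (`time_min`, `well`, `od_raw`, `od`, `group`).
#' @export
plate_od <- function(run, active = TRUE) {
  stopifnot(inherits(run, "plate_run"))
  od <- if (active) active_od(run) else run$od
  od$group <- unname(well_groups(run)[od$well])
  od
}

#' Subtract the per-plate optical-density background
#'
#' The measurement background — light occluded by medium and plate, not
#' bacteria — is estimated as the mean raw OD across all wells at time 0 and
#' subtracted from every reading. Idempotent: the corrected signal is always
#' recomputed from the raw readings.
#'
#' @param run A `plate_run`.
#' @return The run with `od` background-corrected and `background` recorded.
#' @export
subtract_background <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  t0 <- min(run$od$time_min)
  if (t0 > 0) stop("no time-0 readings; cannot estimate background", call. = FALSE)
  bg <- mean(run$od$od_raw[run$od$time_min == t0])
  run$background <- bg
  run$od$od <- run$od$od_raw - bg
  run
}

#' Flag growth curves for omission
#'
#' Applies the automatable omission criterion — raw OD600 above 0.125 at 1 h
#' of growth, indicating initial condensation or measurement error — plus a
#' caller-supplied manual exclusion list (anaerobic or contaminated wells,
#' which cannot be detected from the OD trace alone). Flagged wells are
#' excluded from all downstream statistics; counts are recorded in the
#' `qc_summary` attribute.
#'
#' @param run A `plate_run` with at least 1 h of readings.
#' @param manual_exclusions Character vector of well ids to exclude.
#' @param od_cutoff Raw OD cutoff at 1 h (default 0.125).
#' @return The run with `qc` populated.
#' @export
apply_qc_filters <- function(run, manual_exclusions = character(),
                             od_cutoff = 0.125) {
  stopifnot(inherits(run, "plate_run"))
  if (max(run$od$time_min) < 60) stop("QC needs at least 1 h of data", call. = FALSE)
  tt <- sort(unique(run$od$time_min))
  t1h <- tt[which.min(abs(tt - 60))]
  at1h <- dplyr::filter(run$od, .data$time_min == t1h)
  growth_wells <- run$meta$well[!run$meta$blank]
  bad <- at1h$well[at1h$well %in% growth_wells & at1h$od_raw > od_cutoff]
  qc <- dplyr::bind_rows(
    tibble::tibble(well = bad, reason = "raw OD > 0.125 at 1 h"),
    tibble::tibble(well = intersect(manual_exclusions, run$meta$well),
                   reason = "manual exclusion")
  )
  run$qc <- dplyr::distinct(qc, .data$well, .keep_all = TRUE)
  n_growth <- length(growth_wells)
  attr(run, "qc_summary") <- list(
    n_wells = n_growth,
    n_flagged = nrow(run$qc),
    fraction_flagged = nrow(run$qc) / n_growth
  )
  run
}

#' Log-window growth rates at a threshold optical density
#'
#' For each retained growth well, finds the time at which the corrected OD
#' first reaches `od_threshold` (linear interpolation) and fits ordinary
#' least squares to the natural log of the corrected OD over the window of
#' `window` minutes centered there. The pooled growth rate is the unweighted
#' mean of per-well slopes across replicates and inoculum groups.
#' Non-positive corrected OD values are masked for the log fit, never
#' clipped.
#'
#' @param run A background-subtracted `plate_run`.
#' @param od_threshold Threshold corrected OD (default 0.03).
#' @param window Window width, minutes (default 30).
#' @return An object of class `growth_rate_fit`; `tidy()` gives per-well
#'   slopes, `glance()` the pooled rate.
#' @export
log_window_growth_rate <- function(run, od_threshold = 0.03, window = 30) {
  stopifnot(inherits(run, "plate_run"))
  if (is.na(run$background)) {
    stop("subtract the background first (subtract_background())", call. = FALSE)
  }
  od <- active_od(run)
  grp <- well_groups(run)
  t_first <- min(od$time_min)
  fits <- lapply(split(od, od$well), function(d) {
    d <- d[order(d$time_min), ]
    i <- which(d$od >= od_threshold)
    if (!length(i)) return(NULL)  # never reaches threshold: skipped
    i <- i[1]
    t0 <- if (i == 1) d$time_min[1] else {
      d$time_min[i - 1] + (od_threshold - d$od[i - 1]) /
        (d$od[i] - d$od[i - 1]) * (d$time_min[i] - d$time_min[i - 1])
    }
    if (t0 - window / 2 < t_first) {
      stop(sprintf("fit window for well %s starts before the first sample",
                   d$well[1]), call. = FALSE)
    }
    w <- d[d$time_min >= t0 - window / 2 & d$time_min <= t0 + window / 2 &
             d$od > 0, ]
    fit <- stats::lm(log(od) ~ I(time_min / 60), data = w)
    tibble::tibble(well = d$well[1], group = unname(grp[d$well[1]]),
                   t_cross_min = t0,
                   rate_per_hr = unname(stats::coef(fit)[2]),
                   n_points = nrow(w))
  })
  skipped <- sum(vapply(fits, is.null, logical(1)))
  per_well <- dplyr::bind_rows(fits)
  if (!nrow(per_well)) stop("no well reaches the threshold OD", call. = FALSE)
  structure(list(per_well = per_well,
                 pooled_rate = mean(per_well$rate_per_hr),
                 od_threshold = od_threshold, window = window,
                 n_skipped = skipped),
            class = "growth_rate_fit")
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat(sprintf("<growth_rate_fit> pooled rate %.4g /hr (%d wells, OD %.3g, %g-min window)\n",
              x$pooled_rate, nrow(x$per_well), x$od_threshold, x$window))
  invisible(x)
}

#' @method tidy growth_rate_fit
#' @export
tidy.growth_rate_fit <- function(x, ...) x$per_well

#' @method glance growth_rate_fit
#' @export
glance.growth_rate_fit <- function(x, ...) {
  tibble::tibble(pooled_rate_per_hr = x$pooled_rate,
                 n_wells = nrow(x$per_well), n_skipped = x$n_skipped,
                 od_threshold = x$od_threshold, window_min = x$window)
}

#' Temporal standard deviation as a function of threshold optical density
#'
#' For each inoculum group and each OD threshold, extracts interpolated
#' crossing times of the corrected OD trajectories and summarizes them with
#' [tsd_with_ci()]. For stochastic exponential growth the TSD is predicted
#' to be flat across thresholds well above the inoculum (roughly OD
#' 0.01-0.3).
#'
#' @param run A background-subtracted `plate_run`.
#' @param thresholds OD thresholds; default 10 log-spaced values in
#'   0.01-0.3.
#' @param level,n_boot,seed Passed to [tsd_with_ci()] (default 68% level).
#' @return A tibble: `threshold`, `group`, `n_crossed`, `n_excluded`, `tsd`,
#'   `ci_low`, `ci_high` (hours). Class `tsd_threshold_table`.
#' @export
tsd_vs_threshold <- function(run, thresholds = NULL, level = 0.68,
                             n_boot = 1000, seed = NULL) {
  stopifnot(inherits(run, "plate_run"))
  if (is.na(run$background)) {
    stop("subtract the background first (subtract_background())", call. = FALSE)
  }
  if (is.null(thresholds)) thresholds <- exp(seq(log(0.01), log(0.3), length.out = 10))
  if (!is.null(seed)) withr::local_seed(seed)
  od <- active_od(run)
  od$time_hours <- od$time_min / 60
  grp <- well_groups(run)
  od$group <- unname(grp[od$well])
  rows <- list()
  for (g in unique(od$group)) {
    dg <- od[od$group == g, ]
    for (th in thresholds) {
      fs <- tryCatch(
        suppressWarnings(threshold_crossing_times(dg, th, value_col = "od",
                                                  replicate_col = "well")),
        error = function(e) NULL)
      if (is.null(fs) || nrow(fs) < 2) {
        warning(sprintf("group %s: fewer than 2 crossings at OD %.3g; omitted",
                        g, th), call. = FALSE)
        next
      }
      est <- tsd_with_ci(fs, level = level, n_boot = n_boot)
      rows[[length(rows) + 1]] <- tibble::tibble(
        threshold = th, group = g, n_crossed = nrow(fs),
        n_excluded = attr(fs, "n_excluded"),
        tsd = est$tsd, ci_low = est$ci_low, ci_high = est$ci_high)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tsd_threshold_table", class(out))
  attr(out, "level") <- level
  out
}

#' Fit a linear OD-to-CFU standard curve
#'
#' Least-squares line CFU = a * OD + b over calibration measurements, valid
#' inside the calibration OD range (default 0.01-0.6, the plate reader's
#' linear Beer-Lambert regime); conversions outside the range warn.
#'
#' @param od Calibration optical densities (>= 2 distinct values).
#' @param cfu Matching CFU counts.
#' @param range Calibration OD range.
#' @return An object of class `standard_curve`.
#' @export
fit_standard_curve <- function(od, cfu, range = c(0.01, 0.6)) {
  stopifnot(length(od) == length(cfu), length(od) >= 2)
  if (diff(range(od)) == 0) stop("calibration ODs are constant", call. = FALSE)
  fit <- stats::lm(cfu ~ od)
  sl <- unname(stats::coef(fit)[2])
  if (sl <= 0) stop("standard curve has non-positive slope", call. = FALSE)
  structure(list(slope = sl, intercept = unname(stats::coef(fit)[1]),
                 range = range, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> CFU = %.4g * OD %+.4g (valid OD %.3g-%.3g)\n",
              x$slope, x$intercept, x$range[1], x$range[2]))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(slope_cfu_per_od = x$slope, intercept_cfu = x$intercept,
                 od_min = x$range[1], od_max = x$range[2])
}

#' Convert optical density to CFU (and back) with a standard curve
#'
#' @param curve A `standard_curve`.
#' @param od Optical densities to convert.
#' @return CFU counts.
#' @export
od_to_cfu <- function(curve, od) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(od < curve$range[1] | od > curve$range[2])) {
    warning("OD outside the calibration range; extrapolating", call. = FALSE)
  }
  curve$intercept + curve$slope * od
}

#' @rdname od_to_cfu
#' @param cfu CFU counts to convert to OD.
#' @export
cfu_to_od <- function(curve, cfu) {
  stopifnot(inherits(curve, "standard_curve"))
  (cfu - curve$intercept) / curve$slope
}

#' Lag-phase diagnostic: deterministic versus observed crossing times
#'
#' Compares, per inoculum group, the time a lag-free deterministic
#' exponential model (growth rate `mu` from inoculum `n0` CFU) needs to reach
#' the CFU count corresponding to `od_threshold` with the mean observed
#' crossing time. A positive difference (model slower than observation) is
#' evidence against a significant lag phase: a real lag would delay the
#' observed crossings past the lag-free deterministic prediction.
#'
#' @param run A background-subtracted `plate_run`.
#' @param curve A `standard_curve` (threshold must lie inside its range).
#' @param mu Growth rate, 1/hour.
#' @param n0 Mean inoculum size per group: a single number, or a named vector
#'   / data frame (`group`, `n0`) when groups differ.
#' @param od_threshold Threshold corrected OD (default 0.03).
#' @return A tibble: `group`, `n0`, `omega_cfu`, `t_det_hours`,
#'   `mean_observed_hours`, `delta_min` (deterministic minus observed,
#'   minutes).
#' @export
lag_phase_check <- function(run, curve, mu, n0, od_threshold = 0.03) {
  stopifnot(inherits(run, "plate_run"), inherits(curve, "standard_curve"))
  if (od_threshold < curve$range[1] || od_threshold > curve$range[2]) {
    stop("threshold OD outside the standard-curve calibration range", call. = FALSE)
  }
  omega_cfu <- od_to_cfu(curve, od_threshold)
  od <- active_od(run)
  od$time_hours <- od$time_min / 60
  grp <- well_groups(run)
  od$group <- unname(grp[od$well])
  if (is.data.frame(n0)) n0 <- stats::setNames(n0$n0, n0$group)
  purrr::map_dfr(unique(od$group), function(g) {
    n0g <- if (length(n0) == 1 && is.null(names(n0))) n0 else unname(n0[[g]])
    fs <- suppressWarnings(threshold_crossing_times(
      od[od$group == g, ], od_threshold, value_col = "od", replicate_col = "well"))
    t_det <- log(omega_cfu / n0g) / mu
    t_obs <- mean(fs$fpt_hours)
    tibble::tibble(group = g, n0 = n0g, omega_cfu = omega_cfu,
                   t_det_hours = t_det, mean_observed_hours = t_obs,
                   delta_min = 60 * (t_det - t_obs))
  })
}
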