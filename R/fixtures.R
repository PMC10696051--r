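#' Configuration for a synthetic plate-reader dataset
#'
#' Describes a synthetic 96-well-style growth experiment: per-group inocula
#' (exact or Poisson — untruncated, so wells can receive zero cells and never
#' grow), a stochastic growth model, logistic saturation at a carrying
#' capacity, a linear OD-per-CFU map in the Beer-Lambert regime, a per-plate
#' baseline and additive Gaussian measurement noise.
#'
#' @param model `"sbp"`, `"age"` or `"deterministic"`.
#' @param mu Growth rate, 1/hour (used by `"sbp"` and `"deterministic"`).
#' @param law A [division_time_law()] (used by `"age"`).
#' @param inocula Named numeric vector: one entry per inoculum group, the
#'   Poisson shape (or exact size when `inoculum_kind = "exact"`). Names
#'   become group labels.
#' @param inoculum_kind `"poisson"` (default) or `"exact"`.
#' @param wells_per_group Replicate wells per group.
#' @param n_blank Number of blank (uninoculated) control wells.
#' @param od_per_cfu OD600 per individual; default anchored so OD 0.03
#'   corresponds to 1.4e7 CFU.
#' @param baseline Per-plate background OD (typical plates read 0.099-0.121
#'   at time 0).
#' @param noise_sd Additive Gaussian measurement noise on OD (default 0.001,
#'   a typical plate-reader resolution).
#' @param read_interval_min Reading interval, minutes (2-3 typical).
#' @param horizon_hours Run length, hours.
#' @param carrying_od Corrected OD at carrying capacity (saturation level).
#' @param stochastic_cap Population size beyond which stochastic growth is
#'   continued deterministically.
#' @param lag_min Planted lag phase, minutes (0 = none).
#' @param seed Integer seed for the generator.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(model = c("sbp", "age", "deterministic"),
                           mu = 1.8, law = NULL,
                           inocula = c(low = 2.8, mid = 16, high = 80),
                           inoculum_kind = c("poisson", "exact"),
                           wells_per_group = 42, n_blank = 6,
                           od_per_cfu = 0.03 / 1.4e7,
                           baseline = 0.11, noise_sd = 0.001,
                           read_interval_min = 2, horizon_hours = 24,
                           carrying_od = 0.43, stochastic_cap = 500,
                           lag_min = 0, seed = 1L) {
  model <- match.arg(model)
  inoculum_kind <- match.arg(inoculum_kind)
  if (model == "age" && is.null(law)) {
    law <- division_time_law("stage-structured", 20, 25)
  }
  stopifnot(od_per_cfu > 0, baseline >= 0, noise_sd >= 0,
            read_interval_min > 0, horizon_hours > 0, carrying_od > 0,
            all(inocula > 0), wells_per_group >= 1)
  if (is.null(names(inocula))) names(inocula) <- paste0("g", seq_along(inocula))
  structure(list(model = model, mu = mu, law = law, inocula = inocula,
                 inoculum_kind = inoculum_kind,
                 wells_per_group = wells_per_group, n_blank = n_blank,
                 od_per_cfu = od_per_cfu, baseline = baseline,
                 noise_sd = noise_sd, read_interval_min = read_interval_min,
                 horizon_hours = horizon_hours, carrying_od = carrying_od,
                 stochastic_cap = stochastic_cap, lag_min = lag_min,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# abundance of one well on an hour grid; exact stochastic growth to the cap,
# deterministic continuation beyond, logistic saturation toward K
fixture_abundance <- function(config, k, grid_hours) {
  if (k == 0) return(rep(0, length(grid_hours)))
  cap <- config$stochastic_cap
  tg <- pmax(grid_hours - config$lag_min / 60, 0)
  if (config$model == "deterministic") {
    mu <- config$mu
    n <- k * exp(mu * tg)
  } else if (config$model == "sbp") {
    mu <- config$mu
    ev <- sbp_event_times(mu, k, cap)
    n <- k + findInterval(tg, ev)
    if (length(ev) && k + length(ev) >= cap) {
      t_cap <- ev[length(ev)]
      over <- tg > t_cap
      n[over] <- (k + length(ev)) * exp(mu * (tg[over] - t_cap))
    }
  } else {
    mean_h <- config$law$mean_division_time / 60
    mu <- 60 * malthusian_rate(config$law)
    ev <- bh_events_cpp(as.integer(k), cap, config$law$stages, mean_h,
                        "uniform", mean_h)
    n <- k + findInterval(tg, ev)
    if (length(ev) && k + length(ev) >= cap) {
      t_cap <- ev[length(ev)]
      over <- tg > t_cap
      n[over] <- (k + length(ev)) * exp(mu * (tg[over] - t_cap))
    }
  }
  K <- config$carrying_od / config$od_per_cfu
  # exactly exponential below 40% of carrying capacity, logistic slowdown
  # above, saturating at K
  lo <- n <= 0.4 * K
  out <- n
  out[!lo] <- K * n[!lo] / (K + n[!lo] - 0.4 * K)
  out
}

#' Generate a synthetic plate run with known ground truth
#'
#' Draws per-well inocula, simulates abundance trajectories under the
#' configured growth model, saturates them logistically at the carrying
#' capacity, maps abundance to OD600 linearly, adds the plate baseline and
#' measurement noise, and samples on the reading grid. The returned ground
#' truth records the generating growth rate, every well's inoculum, and the
#' noiseless crossing times at a reference OD.
#'
#' @param config A [fixture_config()].
#' @param truth_od_threshold Corrected OD at which noiseless ground-truth
#'   crossing times are recorded (default 0.03).
#' @return A list: `run` (a `plate_run`) and `truth` (list with `mu_true`
#'   in 1/hour, `inocula`, `crossings`, `config`).
#' @export
generate_plate <- function(config, truth_od_threshold = 0.03) {
  stopifnot(inherits(config, "fixture_config"))
  withr::local_seed(config$seed)
  grid_min <- seq(0, config$horizon_hours * 60, by = config$read_interval_min)
  grid_hours <- grid_min / 60
  mu_true <- if (config$model == "age") 60 * malthusian_rate(config$law) else config$mu
  reach_h <- log(truth_od_threshold / config$od_per_cfu) / mu_true + config$lag_min / 60
  if (config$horizon_hours < reach_h) {
    warning("horizon may be too short for wells to reach the reference OD",
            call. = FALSE)
  }
  wells <- list(); meta <- list(); truths <- list()
  w <- 0L
  for (g in names(config$inocula)) {
    val <- config$inocula[[g]]
    for (r in seq_len(config$wells_per_group)) {
      w <- w + 1L
      id <- sprintf("W%02d", w)
      k <- if (config$inoculum_kind == "exact") as.integer(val)
           else stats::rpois(1, val)
      ab <- fixture_abundance(config, k, grid_hours)
      clean <- config$od_per_cfu * ab
      noisy <- config$baseline + clean +
        stats::rnorm(length(clean), sd = config$noise_sd)
      wells[[id]] <- noisy
      meta[[id]] <- tibble::tibble(well = id, group = g, blank = FALSE)
      cross <- if (any(clean >= truth_od_threshold)) {
        i <- which(clean >= truth_od_threshold)[1]
        if (i == 1) grid_hours[1] else
          grid_hours[i - 1] + (truth_od_threshold - clean[i - 1]) /
            (clean[i] - clean[i - 1]) * (grid_hours[i] - grid_hours[i - 1])
      } else NA_real_
      truths[[id]] <- tibble::tibble(well = id, group = g, inoculum = k,
                                     t_cross_hours = cross)
    }
  }
  for (b in seq_len(config$n_blank)) {
    w <- w + 1L
    id <- sprintf("W%02d", w)
    wells[[id]] <- config$baseline +
      stats::rnorm(length(grid_hours), sd = config$noise_sd)
    meta[[id]] <- tibble::tibble(well = id, group = "blank", blank = TRUE)
  }
  od_wide <- tibble::as_tibble(c(list(time_min = grid_min), wells))
  run <- plate_run(od_wide, dplyr::bind_rows(meta),
                   metadata = list(model = config$model, seed = config$seed))
  truth_tbl <- dplyr::bind_rows(truths)
  list(run = run,
       truth = list(mu_true = mu_true,
                    inocula = truth_tbl[c("well", "group", "inoculum")],
                    crossings = truth_tbl,
                    od_threshold = truth_od_threshold,
                    config = config))
}

#' Generate synthetic spot-plating colony counts
#'
#' Emulates inferring the inoculum distribution by spot plating identical
#' volumes of dilute culture: i.i.d. Poisson counts (untruncated — spots can
#' show zero colonies). The summary attribute reports the zero fraction and
#' the zero-truncated mean of the nonzero counts, the quantity used as the
#' mean inoculum size of growing wells.
#'
#' @param shape Poisson mean (>= 0; 0 gives all-zero counts).
#' @param n_spots Number of spots (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble (`spot`, `count`) with a `summary` attribute.
#' @export
generate_spot_counts <- function(shape, n_spots, seed = NULL) {
  stopifnot(shape >= 0, n_spots >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- stats::rpois(n_spots, shape)
  out <- tibble::tibble(spot = seq_len(n_spots), count = counts)
  attr(out, "summary") <- list(
    mean = mean(counts),
    zero_fraction = mean(counts == 0),
    zt_mean = if (any(counts > 0)) mean(counts[counts > 0]) else NA_real_,
    n_spots = n_spots
  )
  out
}
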