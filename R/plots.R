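#' Plot a plate run
#'
#' Corrected (or raw, if the background has not been subtracted) OD
#' trajectories, one line per well, colored by inoculum group; flagged wells
#' are drawn dashed.
#'
#' @param object A `plate_run`.
#' @param log_od Plot OD on a log scale (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plate_run
#' @export
autoplot.plate_run <- function(object, log_od = TRUE, ...) {
  od <- object$od
  grp <- well_groups(object)
  od$group <- unname(grp[od$well])
  od$flagged <- od$well %in% flagged_wells(object)
  od$signal <- if (is.na(object$background)) od$od_raw else od$od
  p <- ggplot2::ggplot(od, ggplot2::aes(x = .data$time_min / 60,
                                        y = .data$signal,
                                        group = .data$well,
                                        color = .data$group,
                                        linetype = .data$flagged)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "Time (h)",
                  y = if (is.na(object$background)) "Raw OD600" else "Corrected OD600",
                  color = "Group")
  if (log_od) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a first-passage-time sample
#'
#' Histogram of replicate first-passage times.
#'
#' @param object An `fpt_sample`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fpt_sample
#' @export
autoplot.fpt_sample <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpt_hours)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", color = "white") +
    ggplot2::labs(x = "First-passage time (h)", y = "Replicates")
}

#' Plot TSD against threshold optical density
#'
#' @param object A `tsd_threshold_table` from [tsd_vs_threshold()].
#' @param ... Unused.
#' @return A ggplot object with log-scaled threshold axis.
#' @method autoplot tsd_threshold_table
#' @export
autoplot.tsd_threshold_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$tsd,
                                       color = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Threshold OD600", y = "TSD (h)", color = "Group")
}

#' Plot TSD against inoculum size
#'
#' Log-log plot of TSD versus (mean) inoculum size across models; a -1/2
#' power-law guide line can be added.
#'
#' @param tbl A tibble with columns `inoculum`, `tsd` and optionally `model`,
#'   `ci_low`, `ci_high`.
#' @param guide Add a reference line of slope -1/2 (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_tsd_scaling <- function(tbl, guide = TRUE) {
  stopifnot(all(c("inoculum", "tsd") %in% names(tbl)))
  aes <- if ("model" %in% names(tbl)) {
    ggplot2::aes(x = .data$inoculum, y = .data$tsd, color = .data$model)
  } else {
    ggplot2::aes(x = .data$inoculum, y = .data$tsd)
  }
  p <- ggplot2::ggplot(tbl, aes) + ggplot2::geom_point()
  if (all(c("ci_low", "ci_high") %in% names(tbl))) {
    p <- p + ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low,
                                                  ymax = .data$ci_high))
  }
  if (guide) {
    ref <- tbl$tsd[1] * sqrt(tbl$inoculum[1])
    p <- p + ggplot2::geom_function(fun = function(x) ref / sqrt(x),
                                    linetype = "dashed", color = "grey40")
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Mean inoculum size", y = "TSD (h)")
}

#' Plot a growth-rate precision curve
#'
#' Median noise-based growth-rate estimate and bootstrap interval against
#' the number of replicate trajectories.
#'
#' @param curve Output of [precision_curve()].
#' @param mu_true Optional true growth rate to draw as a reference line.
#' @return A ggplot object.
#' @export
plot_precision_curve <- function(curve, mu_true = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$m, y = .data$mu_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "Number of replicate trajectories",
                  y = expression(hat(mu) ~ "(1/hr)"))
  if (!is.null(mu_true)) {
    p <- p + ggplot2::geom_hline(yintercept = mu_true, linetype = "dashed",
                                 color = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
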