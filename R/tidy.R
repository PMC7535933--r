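#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a test result into broom-style columns
#'
#' @param x A `test_result`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `parameter`, `p.value`, `method`.
#' @method tidy test_result
#' @export
tidy.test_result <- function(x, ...) {
  tibble(statistic = x$statistic, parameter = x$df,
         p.value = x$p_value, method = x$test)
}

#' One-row summary of a cell analysis
#'
#' @param x A `cell_analysis`.
#' @param ... Unused.
#' @return One-row tibble: detected events plus per-phase distance means.
#' @method glance cell_analysis
#' @export
glance.cell_analysis <- function(x, ...) {
  ph <- x$phase_summary
  p1 <- ph[ph$phase == "I", ]
  p2 <- ph[ph$phase == "II", ]
  dplyr::bind_cols(
    x$events,
    tibble(mean_d_xy_I = p1$mean_d_xy, mean_d_xy_II = p2$mean_d_xy,
           mean_d_z_I = p1$mean_d_z, mean_d_z_II = p2$mean_d_z)
  )
}

#' Per-frame table of a cell analysis
#'
#' @param x A `cell_analysis`.
#' @param ... Unused.
#' @return The per-frame tibble.
#' @method tidy cell_analysis
#' @export
tidy.cell_analysis <- function(x, ...) x$per_frame

#' MSD exponent summary
#'
#' @param x An `msd_curve`.
#' @param ... Unused.
#' @return One-row tibble with `alpha` and the fitted lag range.
#' @method glance msd_curve
#' @export
glance.msd_curve <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"),
         fit_lag_min = min(attr(x, "fit_lags")),
         fit_lag_max = max(attr(x, "fit_lags")))
}

#' Plot a cell's centriole trajectories on the apical surface
#'
#' Centre-relative x-y paths of both centrioles, the apical circle, and the
#' polarity axis (arrow toward the lateral periphery).
#'
#' @param truth A `cell_truth`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(truth) {
  stopifnot(inherits(truth, "cell_truth"))
  rel <- detrend_tracks(truth$tracks, truth$center)
  th <- seq(0, 2 * pi, length.out = 120)
  R <- truth$apical_radius
  circ <- tibble(x = R * cos(th), y = R * sin(th))
  ax <- truth$polarity_axis * R
  ggplot2::ggplot(rel, ggplot2::aes(.data$x_um, .data$y_um,
                                    colour = .data$role)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::annotate("segment", x = 0, y = 0, xend = ax[1], yend = ax[2],
                      arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um, centre-relative)",
                  y = "y (um, centre-relative)",
                  colour = NULL,
                  title = sprintf("Centriole trajectories (%s)",
                                  truth$mode_label))
}

#' Plot per-frame distances and signed-axis position
#'
#' @param x A `cell_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_analysis
#' @export
autoplot.cell_analysis <- function(x, ...) {
  pf <- x$per_frame |>
    dplyr::select("t_min", "d_xy", "d_z", "s_dc") |>
    tidyr::pivot_longer(-"t_min")
  entry <- x$events$phase2_entry
  p <- ggplot2::ggplot(pf, ggplot2::aes(.data$t_min / 60, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (hr)", y = NULL)
  if (!is.na(entry)) {
    p <- p + ggplot2::geom_vline(
      xintercept = entry * x$params$frame_interval / 60, linetype = 3)
  }
  p
}

#' Plot an MSD curve on log-log axes
#'
#' @param x An `msd_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(.data$lag_min, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (min)", y = "MSD (um^2)",
                  title = sprintf("alpha = %.2f", attr(x, "alpha")))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
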