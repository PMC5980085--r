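# ggplot2 views of the main result types.

#' @export
autoplot.prd_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$tracks,
    ggplot2::aes(.data$x_um, .data$y_um, group = .data$cell_id,
                 colour = factor(.data$cell_id))
  ) +
    ggplot2::geom_path(show.legend = FALSE, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)),
      title = "Simulated PRD trajectories"
    )
}

#' @export
autoplot.contour_frame <- function(object, ...) {
  cen <- attr(object, "centroid")
  df <- tibble::tibble(
    x = cen[["x"]] + object$r * cos(object$theta),
    y = cen[["y"]] + object$r * sin(object$theta)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m)))
}

#' Plot an ensemble MSD on log-log axes
#'
#' @param msd_tbl Output of [msd()].
#' @param fit Optional [fit_prw()] object whose curve is overlaid.
#' @return A ggplot object.
#' @export
plot_msd <- function(msd_tbl, fit = NULL) {
  g <- ggplot2::ggplot(msd_tbl, ggplot2::aes(.data$lag_min, .data$msd)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "lag (min)", y = expression(MSD ~ (mu * m^2)),
      title = "Mean squared displacement"
    )
  if (!is.null(fit)) {
    g <- g + ggplot2::geom_line(
      data = fit$fitted, ggplot2::aes(y = .data$fitted), colour = "grey40"
    )
  }
  g
}

#' Histogram of rotation angles between persistent segments
#'
#' @param angles Output of [rotation_angles()].
#' @param binwidth Bin width in degrees (default 20).
#' @return A ggplot object.
#' @export
plot_rotation_angles <- function(angles, binwidth = 20) {
  ggplot2::ggplot(angles, ggplot2::aes(.data$angle_deg)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth, boundary = -binwidth / 2,
      fill = "grey70", colour = "grey30"
    ) +
    ggplot2::labs(
      x = expression(Delta * theta ~ (degree)), y = "density",
      title = "Rotation angle between persistent segments"
    )
}

#' Tile plot of a joint phase distribution
#'
#' @param pjd Output of [phase_joint_distribution()].
#' @return A ggplot object.
#' @export
plot_phase_joint <- function(pjd) {
  ggplot2::ggplot(
    pjd$density,
    ggplot2::aes(.data$arg_a, .data$arg_b, fill = .data$prob)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "arg(a)", y = "arg(b)", fill = "prob")
}

#' Binned predicted-vs-observed velocity plot
#'
#' @param binned Output of [binned_velocity_agreement()].
#' @return A ggplot object with the identity line.
#' @export
plot_binned_agreement <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(.data$center, .data$mean_obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_obs - .data$sd_obs,
      ymax = .data$mean_obs + .data$sd_obs
    ), size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component)) +
    ggplot2::labs(
      x = expression(predicted ~ v ~ (mu * m ~ h^-1)),
      y = expression(observed ~ V ~ (mu * m ~ h^-1))
    )
}
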