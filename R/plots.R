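## ggplot2 views of the main result types.

#' Plot a target set
#'
#' Front (y-z) and side (x-z) views of the target centres, coloured by
#' pick/place role, with arrows indicating the projected hand axis.
#'
#' @param targets A `target_set` tibble.
#' @param axis_len Arrow length in metres.
#' @return A ggplot object.
#' @export
plot_targets <- function(targets, axis_len = 0.05) {
  targets <- as_tibble(targets)
  ax <- spherical_to_axis(targets$incl, targets$azim)
  long <- dplyr::bind_rows(
    tibble(
      view = "front (y-z)", h = targets$y, v = targets$z,
      dh = ax[, "y"] * axis_len, dv = ax[, "z"] * axis_len,
      role = targets$role
    ),
    tibble(
      view = "side (x-z)", h = targets$x, v = targets$z,
      dh = ax[, "x"] * axis_len, dv = ax[, "z"] * axis_len,
      role = targets$role
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v, colour = .data$role)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$h + .data$dh, yend = .data$v + .data$dv),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))
    ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "position (m)", y = "position (m)", colour = NULL)
}

#' @export
autoplot.target_set <- function(object, ...) plot_targets(object, ...)

#' @export
autoplot.arm_session <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$samples[c("t", ANGLE_COLS)],
    dplyr::all_of(ANGLE_COLS),
    names_to = "dof", values_to = "angle"
  )
  long$dof <- factor(long$dof, levels = ANGLE_COLS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = rad2deg(.data$angle))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~dof, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)")
}

#' @export
autoplot.phase_result <- function(object, ...) {
  trials <- object$trials
  ggplot2::ggplot(
    trials[trials$success, ],
    ggplot2::aes(x = .data$movement_time)
  ) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0) +
    ggplot2::labs(
      x = "movement time (s)", y = "trials",
      title = sprintf(
        "%.1f%% success, median MT %.2f s",
        success_rate(trials), median(movement_times(trials))
      )
    )
}
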