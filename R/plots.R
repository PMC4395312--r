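# ggplot2 views of traces, pools and cohort tables.

ellipse_path <- function(center, semi_axes, angle, k = 1, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  R <- rotation2(angle)
  xy <- cbind(k * semi_axes[1] * cos(t), k * semi_axes[2] * sin(t)) %*% t(R)
  tibble::tibble(x = xy[, 1] + center[1], y = xy[, 2] + center[2])
}

#' Plot a scatter result as a point cloud with its covariance ellipse
#'
#' @param object A `scatter_result` from [scatter_index()].
#' @param points Optional data frame of the underlying neuron coordinates
#'   (`x`, `y`) to overlay.
#' @param k Ellipse radius in units of the directional SDs (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scatter_result <- function(object, points = NULL, k = 1, ...) {
  ell <- ellipse_path(object$center, object$semi_axes, object$angle, k = k)
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(x = .data$x, y = .data$y),
      alpha = 0.6, size = 0.9)
  }
  p +
    ggplot2::geom_path(data = ell, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "firebrick") +
    ggplot2::annotate("point", x = object$center[1], y = object$center[2],
                      shape = 3, color = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "medio-lateral (hemicord units)",
      y = "dorso-ventral (hemicord units)",
      title = sprintf("SI = %.3g (n = %d)", object$si, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the sections of a trace series
#'
#' Overlays neurons, lateral-edge landmarks, optical reference points and
#' central canals of all sections in one coronal view; useful before/after
#' alignment.
#'
#' @param series A trace tibble.
#' @return A ggplot object.
#' @export
plot_series <- function(series) {
  pts <- dplyr::filter(series, .data$record_type != "axis")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      ggplot2::aes(color = .data$pool_label, shape = .data$record_type),
      alpha = 0.7, size = 1.2) +
    ggplot2::scale_shape_manual(
      values = c(neuron = 16, lateral_edge = 2, central_canal = 3,
                 optical_ref = 0),
      na.translate = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medio-lateral", y = "dorso-ventral",
                  color = "pool", shape = "record") +
    ggplot2::theme_minimal()
}

#' Plot longitudinal ladder-rung performance
#'
#' Group mean ± SEM of crossing time (or slips) over the test timepoints.
#'
#' @param behavior A behavior tibble (see [sim_cohort()]).
#' @param metric `"crossing_time_s"` or `"slips"`.
#' @return A ggplot object.
#' @export
plot_behavior <- function(behavior, metric = c("crossing_time_s", "slips")) {
  metric <- match.arg(metric)
  summ <- behavior |>
    dplyr::group_by(.data$housing, .data$genotype, .data$timepoint_weeks) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     sem = sem(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$timepoint_weeks, y = .data$mean,
    color = .data$genotype, group = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$housing)) +
    ggplot2::labs(x = "age (weeks)",
                  y = if (metric == "slips") "slips per crossing"
                      else "crossing time (s)") +
    ggplot2::theme_minimal()
}
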