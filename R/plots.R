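# ggplot2 methods for the package's result types.

#' @export
autoplot.compass_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$midpoint_deg, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_end[1] - object$bin_start[1],
                      fill = "steelblue", colour = "grey30") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, 45)) +
    ggplot2::labs(x = "displacement angle (deg, 90 = toward surface)",
                  y = "trials",
                  title = attr(object, "group"))
}

#' @export
autoplot.velocity_heatmap <- function(object, fish = NULL, ...) {
  df <- as_tibble(object)
  clips <- attr(object, "clips")
  if (!is.null(fish)) {
    df <- filter(df, .data$fish_id == fish)
    clips <- filter(clips, .data$fish_id == fish)
  }
  lims <- c(min(clips$clip_low_value), max(clips$clip_high_value))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$second, y = .data$trial,
                                        fill = .data$v_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = lims, oob = scales_squish) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "trial time (s)", y = "trial",
                  fill = "upward\nvelocity (px/s)")
  if ("fish_id" %in% names(df) && is.null(fish)) {
    p <- p + ggplot2::facet_wrap(~fish_id)
  }
  p
}

# clamp out-of-bounds values to the limits (avoids a scales dependency)
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' @export
autoplot.hazard_curve <- function(object, ...) {
  ggplot2::ggplot(filter(object, !is.na(.data$ln_hazard)),
                  ggplot2::aes(x = .data$bin_mid, y = .data$ln_hazard)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age (days)", y = "ln hazard")
}

#' @export
autoplot.gompertz_fit <- function(object, bin_width = 27, ...) {
  hz <- binned_hazard(object$data, bin_width)
  # fitted ln hazard per bin: ln(H(t+w) - H(t)) approximates the discrete
  # per-bin death probability on the day scale
  a <- object$rate_per_day; b <- object$shape_per_day
  tt <- seq(0, max(object$data$lifespan_days), length.out = 200)
  fit_line <- tibble(t = tt, ln_h = log(a * bin_width) + b * tt)
  autoplot(hz) +
    ggplot2::geom_line(data = fit_line,
                       ggplot2::aes(x = .data$t, y = .data$ln_h),
                       colour = "firebrick") +
    ggplot2::labs(
      subtitle = sprintf("rate of aging b = %.4f per %g d (%.4f, %.4f)",
                         object$shape, object$time_unit,
                         object$ci_shape[1], object$ci_shape[2]))
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$boot, ggplot2::aes(x = .data$enrichment)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$enrichment,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "control-set enrichment",
                  y = "bootstrap sets",
                  title = sprintf(
                    "observed %.3f vs bootstrap median %.3f (B = %d)",
                    object$enrichment, object$boot_median_enrichment,
                    object$B))
}

#' Plot a fish trajectory relative to the food-drop site
#'
#' @param tracks (Preprocessed) track table.
#' @param fish,trial Which track to draw.
#' @param keypoint Keypoint to draw.
#' @param fps Frames per second (for the colour scale).
#' @return A ggplot: the path coloured by time, with the food-drop and
#'   red-light sites marked.
#' @export
plot_trajectory <- function(tracks, fish, trial, keypoint = "head",
                            fps = NULL) {
  fps <- track_fps(tracks, fps)
  df <- as_tibble(tracks) |>
    filter(.data$fish_id == fish, .data$trial == !!trial)
  marks <- df |>
    filter(.data$keypoint %in% c("food_drop", "red_light")) |>
    group_by(.data$keypoint) |>
    summarise(x = mean(.data$x[.data$likelihood > 0.95], na.rm = TRUE),
              y = mean(.data$y[.data$likelihood > 0.95], na.rm = TRUE),
              .groups = "drop")
  path <- filter(df, .data$keypoint == !!keypoint)
  ggplot2::ggplot(path, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$frame / fps)) +
    ggplot2::geom_path(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(shape = .data$keypoint),
                        colour = "black", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(colour = "time (s)", shape = NULL,
                  x = "x (px)", y = "y (px, image convention)")
}
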