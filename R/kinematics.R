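# Frame-level kinematics: upward velocity, rolling averages, winsorized
# per-animal means, displacement angles and compass histograms.
#
# Image convention throughout: pixel origin top-left, y increases downward.
# "Upward" (toward the water surface) is therefore -delta(y); upward
# velocity is positive when the fish moves toward the surface.

#' Per-frame kinematics of a track
#'
#' Computes, per track, the upward instantaneous velocity
#' `v_up[i] = -(y[i] - y[i-1]) * fps` (px/s, positive toward the surface), a
#' centred rolling average over `window` frames, and -- when a food-drop
#' site is supplied -- the Euclidean distance to it.
#'
#' For an even window the average spans `window/2 - 1` frames back and
#' `window/2` frames forward; any missing frame in the window, or an
#' incomplete window at the edges, yields `NA`.
#'
#' @param tracks (Preprocessed) long track table.
#' @param keypoint Keypoint to analyse.
#' @param window Rolling-average width in frames (default 20, i.e. 1 s at
#'   20 fps).
#' @param site Optional food-drop site: either a `c(x=, y=)` vector or the
#'   per-fish tibble returned by [locate_food_drop()].
#' @param fps Frames per second; defaults to the table's `fps` attribute.
#' @return A tibble with the grouping columns, `frame`, `t` (s), `x`, `y`,
#'   `v_up`, `v_up_rolled`, and `dist_food` if `site` was given.
#' @export
track_kinematics <- function(tracks, keypoint = "head", window = 20,
                             site = NULL, fps = NULL) {
  stopifnot(window >= 1)
  fps <- track_fps(tracks, fps)
  gb <- track_groups(tracks)
  kin <- as_tibble(tracks) |>
    filter(.data$keypoint == !!keypoint) |>
    select(all_of(gb), "frame", "x", "y") |>
    group_by(across(all_of(gb))) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(
      t = .data$frame / fps,
      v_up = -(.data$y - lag(.data$y)) * fps,
      v_up_rolled = roll_mean_centered(.data$v_up, window)
    ) |>
    ungroup()
  if (!is.null(site)) {
    if (is.data.frame(site)) {
      kin <- kin |>
        left_join(select(site, "fish_id", sx = "x", sy = "y"),
                  by = "fish_id") |>
        mutate(dist_food = sqrt((.data$x - .data$sx)^2 +
                                  (.data$y - .data$sy)^2)) |>
        select(-"sx", -"sy")
    } else {
      kin <- mutate(kin, dist_food = sqrt((.data$x - site[["x"]])^2 +
                                            (.data$y - site[["y"]])^2))
    }
  }
  attr(kin, "fps") <- fps
  attr(kin, "window") <- window
  kin
}

# Centred moving average; even windows take one extra frame forward.
# NA whenever the window is incomplete or contains a missing value.
roll_mean_centered <- function(v, window) {
  n <- length(v)
  if (window > n) {
    warn("Rolling window longer than series; all values missing.")
    return(rep(NA_real_, n))
  }
  if (window == 1L) return(v)
  back <- (window - 1L) %/% 2L
  fwd <- window - 1L - back
  out <- rep(NA_real_, n)
  lo <- 1L + back
  hi <- n - fwd
  if (lo > hi) return(out)
  cs <- cumsum(ifelse(is.na(v), 0, v))
  nas <- cumsum(is.na(v))
  i <- lo:hi
  a <- i - back
  b <- i + fwd
  tot <- cs[b] - c(0, cs)[a]
  nna <- nas[b] - c(0, nas)[a]
  out[i] <- ifelse(nna > 0L, NA_real_, tot / window)
  out
}

#' Rolling average of an already-computed velocity series
#'
#' Convenience wrapper that (re)computes `v_up_rolled` on a kinematics
#' table, e.g. with a different window.
#'
#' @param kin A kinematics tibble from [track_kinematics()].
#' @param window Window width in frames.
#' @return `kin` with `v_up_rolled` replaced.
#' @export
rolling_velocity <- function(kin, window = 20) {
  stopifnot(window >= 1)
  gb <- track_groups(kin)
  out <- kin |>
    group_by(across(all_of(gb))) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(v_up_rolled = roll_mean_centered(.data$v_up, window)) |>
    ungroup()
  attr(out, "fps") <- attr(kin, "fps")
  attr(out, "window") <- window
  out
}

#' Winsorized mean upward velocity per animal
#'
#' Pools every rolled velocity of an animal across all its trials, caps
#' values beyond the `cap` and `1 - cap` percentiles to those percentile
#' values, and averages. The capping keeps isolated tracking glitches from
#' dominating an animal's average activity.
#'
#' @param kin Kinematics tibble covering one or more fish.
#' @param cap Fraction winsorized in each tail, in `[0, 0.5)`; `cap = 0` is
#'   the plain mean.
#' @return A tibble with one row per fish: `fish_id`, `n_frames`,
#'   `mean_v_up` (px/s).
#' @export
winsorized_mean_velocity <- function(kin, cap = 0.15) {
  stopifnot(cap >= 0, cap < 0.5)
  gb <- if ("fish_id" %in% names(kin)) "fish_id" else character()
  res <- kin |>
    filter(!is.na(.data$v_up_rolled)) |>
    group_by(across(all_of(gb))) |>
    summarise(
      n_frames = dplyr::n(),
      mean_v_up = {
        v <- .data$v_up_rolled
        lo <- pctl(v, cap); hi <- pctl(v, 1 - cap)
        mean(pmin(pmax(v, lo), hi))
      },
      .groups = "drop"
    )
  if (nrow(res) == 0L) abort("Empty velocity pool.")
  res
}

#' Displacement angle between two trial times
#'
#' Angle of the vector from the position at `t_start` to the position at
#' `t_end` (nearest frames), on upward-positive axes: 0 deg is rightward,
#' 90 deg is straight up toward the surface.
#'
#' @param tracks (Preprocessed) track table.
#' @inheritParams track_kinematics
#' @param t_start,t_end Endpoint times in seconds (defaults 2 and 9: light
#'   onset and food arrival).
#' @return A tibble with the grouping columns and `angle_deg` in `[0, 360)`;
#'   `NA` when either endpoint position is missing.
#' @export
displacement_angle <- function(tracks, t_start = 2, t_end = 9,
                               keypoint = "head", fps = NULL) {
  fps <- track_fps(tracks, fps)
  gb <- track_groups(tracks)
  as_tibble(tracks) |>
    filter(.data$keypoint == !!keypoint) |>
    group_by(across(all_of(gb))) |>
    summarise(
      angle_deg = {
        f1 <- .data$frame[which.min(abs(.data$frame - t_start * fps))]
        f2 <- .data$frame[which.min(abs(.data$frame - t_end * fps))]
        p1 <- c(.data$x[.data$frame == f1], .data$y[.data$frame == f1])
        p2 <- c(.data$x[.data$frame == f2], .data$y[.data$frame == f2])
        if (anyNA(c(p1, p2))) NA_real_ else {
          (atan2(-(p2[2] - p1[2]), p2[1] - p1[1]) * 180 / pi) %% 360
        }
      },
      .groups = "drop"
    )
}

#' Bin displacement angles into a compass histogram
#'
#' @param angles Numeric vector of angles in degrees (or a tibble from
#'   [displacement_angle()], whose `angle_deg` column is used). `NA` angles
#'   are dropped and counted in the `n_missing` attribute.
#' @param bin_width Bin width in degrees; must divide 360. Bin edges sit at
#'   multiples of `bin_width` starting from 0.
#' @param group Optional label (e.g. `"early"`/`"late"`) stored on the
#'   result.
#' @return A tibble of class `compass_histogram` with `bin_start`,
#'   `bin_end`, `midpoint_deg`, `count`.
#' @export
compass_histogram <- function(angles, bin_width = 20, group = NULL) {
  if (is.data.frame(angles)) angles <- angles$angle_deg
  if (360 %% bin_width != 0) abort("bin_width must divide 360.")
  n_missing <- sum(is.na(angles))
  a <- angles[!is.na(angles)] %% 360
  edges <- seq(0, 360 - bin_width, by = bin_width)
  idx <- floor(a / bin_width) + 1L
  counts <- tabulate(idx, nbins = length(edges))
  out <- tibble(
    bin_start = edges,
    bin_end = edges + bin_width,
    midpoint_deg = edges + bin_width / 2,
    count = counts
  )
  attr(out, "group") <- group
  attr(out, "n_missing") <- n_missing
  class(out) <- c("compass_histogram", class(out))
  out
}

#' Per-trial, per-second velocity matrix with heatmap clip bounds
#'
#' Averages the rolled upward velocity within each (trial, second) cell.
#' The per-animal clip bounds -- the `1 - clip_high` and `clip_low` pooled
#' percentiles -- are reported as plotting metadata only; cell values are
#' never altered.
#'
#' @param kin Kinematics tibble for one or more fish.
#' @param clip_high,clip_low Fractions of the velocity distribution mapped
#'   to the colour-scale extremes (defaults 0.07 and 0.10).
#' @return A tibble of class `velocity_heatmap` (`fish_id`, `trial`,
#'   `second`, `v_mean`) with a `clips` attribute (per-fish bounds).
#' @export
velocity_heatmap <- function(kin, clip_high = 0.07, clip_low = 0.10) {
  gb <- if ("fish_id" %in% names(kin)) "fish_id" else character()
  cells <- kin |>
    mutate(second = floor(.data$t)) |>
    group_by(across(all_of(c(gb, "trial", "second")))) |>
    summarise(v_mean = mean(.data$v_up_rolled, na.rm = TRUE),
              .groups = "drop")
  clips <- kin |>
    filter(!is.na(.data$v_up_rolled)) |>
    group_by(across(all_of(gb))) |>
    summarise(clip_low_value = pctl(.data$v_up_rolled, clip_low),
              clip_high_value = pctl(.data$v_up_rolled, 1 - clip_high),
              .groups = "drop")
  attr(cells, "clips") <- clips
  class(cells) <- c("velocity_heatmap", class(cells))
  cells
}

#' @rdname velocity_heatmap
#' @param x A `velocity_heatmap`.
#' @param fish Fish to extract when the table covers several.
#' @return `heatmap_matrix()`: a trial-by-second numeric matrix.
#' @export
heatmap_matrix <- function(x, fish = NULL) {
  df <- as_tibble(x)
  if (!is.null(fish)) df <- filter(df, .data$fish_id == fish)
  wide <- df |>
    select("trial", "second", "v_mean") |>
    pivot_wider(names_from = "second", values_from = "v_mean") |>
    arrange(.data$trial)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$trial
  m
}
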