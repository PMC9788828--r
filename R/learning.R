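# Associative-learning quantification: food-drop localization, surface
# arrivals, velocity bursts, t1 extraction with edge rules, success calls,
# learning index, manual-score t1 and per-fish summaries.

#' Locate the food-drop site for each fish
#'
#' Per video (trial), the food-drop keypoint coordinate at its maximum
#' likelihood is taken; the site is the mean of those per-video coordinates.
#' Videos in which the keypoint never has positive likelihood are excluded.
#'
#' @param tracks Long track table containing a `food_drop` keypoint.
#' @param keypoint Name of the food-drop keypoint.
#' @return A tibble with one row per fish: `fish_id`, `x`, `y`,
#'   `n_videos_used`.
#' @export
locate_food_drop <- function(tracks, keypoint = "food_drop") {
  if (!keypoint %in% tracks$keypoint) {
    abort(paste0("Keypoint '", keypoint, "' absent from tracks."))
  }
  gb <- track_groups(tracks)
  per_video <- as_tibble(tracks) |>
    filter(.data$keypoint == !!keypoint) |>
    group_by(across(all_of(gb))) |>
    summarise(
      ok = any(!is.na(.data$likelihood) & .data$likelihood > 0 &
                 !is.na(.data$x)),
      x = if (ok[1]) .data$x[which.max(.data$likelihood)] else NA_real_,
      y = if (ok[1]) .data$y[which.max(.data$likelihood)] else NA_real_,
      .groups = "drop"
    ) |>
    filter(.data$ok)
  if (nrow(per_video) == 0L) {
    abort("Food-drop likelihood is zero in every video.")
  }
  fish_gb <- intersect("fish_id", gb)
  per_video |>
    group_by(across(all_of(fish_gb))) |>
    summarise(x = mean(.data$x), y = mean(.data$y),
              n_videos_used = dplyr::n(), .groups = "drop")
}

#' Times at which the fish arrives at the surface
#'
#' A frame counts as "at the surface" when its distance to the food-drop
#' site is at most `radius` pixels. Contiguous qualifying runs collapse to
#' the time of their first frame.
#'
#' @param kin Kinematics tibble with a `dist_food` column (see
#'   [track_kinematics()]).
#' @param radius Surface radius in pixels; the assay convention allows
#'   100--150 px per animal, default 125.
#' @return A tibble with the grouping columns and `arrival_s`; trials with
#'   no arrival contribute no rows.
#' @export
surface_arrivals <- function(kin, radius = 125) {
  stopifnot(radius > 0)
  if (!"dist_food" %in% names(kin)) {
    abort("kin must carry dist_food; pass a site to track_kinematics().")
  }
  gb <- track_groups(kin)
  kin |>
    group_by(across(all_of(gb))) |>
    arrange(.data$frame, .by_group = TRUE) |>
    reframe({
      at <- !is.na(.data$dist_food) & .data$dist_food <= radius
      tt <- .data$t
      runs <- true_runs(at)
      tibble(arrival_s = tt[runs$start])
    })
}

#' Velocity bursts per trial from a per-animal range threshold
#'
#' The burst threshold for an animal is
#' `v_min + fraction * (v_max - v_min)` over its pooled non-missing rolled
#' velocities (all trials); with the default `fraction = 0.75` bursts are
#' approximately the top quarter of the animal's velocity range. Bursts are
#' maximal runs of frames strictly above threshold.
#'
#' @param kin Kinematics tibble for one or more fish.
#' @param fraction Range fraction in (0, 1); per-animal overrides may be
#'   supplied as a tibble `overrides(fish_id, burst_fraction)`.
#' @param overrides Optional per-animal override tibble.
#' @return A tibble with the grouping columns, `start_s`, `end_s` (frame
#'   times bounding each burst) and a `thresholds` attribute (per-fish
#'   tibble with `burst_threshold` px/s and the fraction used).
#' @export
velocity_bursts <- function(kin, fraction = 0.75, overrides = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  gb <- track_groups(kin)
  fish_gb <- intersect("fish_id", gb)
  pool <- kin |> filter(!is.na(.data$v_up_rolled))
  if (nrow(pool) == 0L) abort("Empty velocity pool.")
  thr <- pool |>
    group_by(across(all_of(fish_gb))) |>
    summarise(v_min = min(.data$v_up_rolled),
              v_max = max(.data$v_up_rolled), .groups = "drop") |>
    mutate(fraction_used = fraction)
  if (!is.null(overrides) && "burst_fraction" %in% names(overrides)) {
    thr <- thr |>
      left_join(select(overrides, "fish_id", "burst_fraction"),
                by = "fish_id") |>
      mutate(fraction_used = dplyr::coalesce(.data$burst_fraction,
                                             .data$fraction_used)) |>
      select(-"burst_fraction")
  }
  thr <- mutate(thr, burst_threshold = .data$v_min +
                  .data$fraction_used * (.data$v_max - .data$v_min))
  kin2 <- if (length(fish_gb)) {
    left_join(kin, select(thr, all_of(fish_gb), "burst_threshold"),
              by = fish_gb)
  } else {
    mutate(kin, burst_threshold = thr$burst_threshold[1])
  }
  bursts <- kin2 |>
    group_by(across(all_of(gb))) |>
    arrange(.data$frame, .by_group = TRUE) |>
    reframe({
      hot <- !is.na(.data$v_up_rolled) &
        .data$v_up_rolled > .data$burst_threshold
      tt <- .data$t
      runs <- true_runs(hot)
      tibble(start_s = tt[runs$start], end_s = tt[runs$end])
    })
  attr(bursts, "thresholds") <-
    select(thr, all_of(fish_gb), "burst_threshold", "fraction_used")
  bursts
}

#' t1 of a single trial from its bursts and arrivals
#'
#' Edge rules, applied in order: a fish already at the surface at its first
#' analysed frame has `t1 = 0`; a trial with no surface arrival has
#' `t1 = trial_end_s`; otherwise `t1` is the start time of the velocity
#' burst closest in time to the first arrival (distance zero if the arrival
#' falls inside the burst; ties go to the earlier burst), or the arrival
#' time itself if the trial has no burst.
#'
#' @param bursts Tibble with `start_s`, `end_s` for the trial (possibly
#'   zero rows).
#' @param arrivals Numeric vector of arrival times (s) for the trial.
#' @param at_surface_start Logical: was the fish within the surface radius
#'   at its first frame with a defined position?
#' @param timing Trial timing constants, see [trial_timing()].
#' @return `t1` in seconds.
#' @export
first_surface_bound_time <- function(bursts, arrivals, at_surface_start,
                                     timing = trial_timing()) {
  if (isTRUE(at_surface_start)) return(0)
  if (length(arrivals) == 0L || all(is.na(arrivals))) {
    return(timing$trial_end_s)
  }
  a <- min(arrivals, na.rm = TRUE)
  if (is.null(bursts) || nrow(bursts) == 0L) return(a)
  gap <- ifelse(a >= bursts$start_s & a <= bursts$end_s, 0,
                pmin(abs(a - bursts$start_s), abs(a - bursts$end_s)))
  cand <- which(gap == min(gap))
  best <- cand[which.min(bursts$start_s[cand])]
  bursts$start_s[best]
}

#' Was a trial successful?
#'
#' A successful trial is one whose first surface-bound trajectory starts in
#' the closed window from light onset to food arrival; a `t1` of 0 (fish
#' already at the surface before the light) is not a success.
#'
#' @param t1 Latency (s), vectorised.
#' @param timing Trial timing constants.
#' @return Logical vector.
#' @export
trial_success <- function(t1, timing = trial_timing()) {
  t1 >= timing$light_on_s & t1 <= timing$food_drop_s
}

#' Learning index of a success sequence
#'
#' The reciprocal of the first trial number that begins a run of `k`
#' consecutive successes, or 0 when no such run exists. Missing success
#' flags (untracked trials) break runs but keep their trial number.
#'
#' @param success Logical vector ordered by trial number.
#' @param k Required number of consecutive successes (default 2).
#' @return A value in `{0} U {1/n}`.
#' @export
#' @examples
#' learning_index(c(FALSE, FALSE, FALSE, TRUE, TRUE)) # 1/4
learning_index <- function(success, k = 2) {
  stopifnot(k >= 1)
  s <- !is.na(success) & success
  n <- length(s)
  if (n < k) return(0)
  for (i in seq_len(n - k + 1L)) {
    if (all(s[i:(i + k - 1L)])) return(1 / i)
  }
  0
}

#' t1 from a manual per-second score sheet
#'
#' Finds the first second at the surface, then backtracks through the
#' maximal unbroken run of upward seconds leading into it; a pause (an
#' upward score of 0 for at least one second) during the ascent restarts
#' the run, so the post-pause ascent is the one reported. A fish that never
#' reaches the surface gets `t1 = trial_end_s`.
#'
#' @param scores Tibble with columns `second`, `upward`, `at_surface`
#'   (see [read_manual_scores()]).
#' @param trial_end_s Trial length in seconds.
#' @return `t1` in whole seconds.
#' @export
manual_t1 <- function(scores, trial_end_s = 18) {
  scores <- arrange(scores, .data$second)
  surf <- scores$second[scores$at_surface == 1]
  if (length(surf) == 0L) return(trial_end_s)
  s <- surf[1]
  up <- setNames(scores$upward, scores$second)
  j <- s
  while (as.character(j - 1) %in% names(up) &&
         !is.na(up[[as.character(j - 1)]]) && up[[as.character(j - 1)]] == 1) {
    j <- j - 1
  }
  j
}

#' Automated t1 extraction for a whole session
#'
#' End-to-end driver: preprocesses the head keypoint (unless
#' `preprocessed = TRUE`), locates the per-fish food-drop site from the raw
#' tracks, computes kinematics, surface arrivals and velocity bursts, and
#' applies the t1 edge rules per trial.
#'
#' @param session A `killicog_session`.
#' @param timing Trial timing constants.
#' @param likelihood_threshold,jump_quantile Prefilter settings.
#' @param window Rolling-average window (frames).
#' @param burst_fraction Velocity-range fraction defining bursts.
#' @param surface_radius Surface radius in px (100--150 by convention).
#' @param overrides Optional per-animal tibble with any of
#'   `burst_fraction`, `surface_radius`; logged in the output columns.
#' @param preprocessed Set `TRUE` if `session` already went through
#'   [preprocess_session()].
#' @return A tibble with one row per (fish, trial): `t1`, `success`,
#'   `method = "auto"`, `burst_threshold_used`, `surface_radius_used`.
#' @export
compute_t1 <- function(session, timing = trial_timing(),
                       likelihood_threshold = 0.999, jump_quantile = 0.05,
                       window = 20, burst_fraction = 0.75,
                       surface_radius = 125, overrides = NULL,
                       preprocessed = FALSE) {
  stopifnot(inherits(session, "killicog_session"))
  site <- locate_food_drop(session$tracks)
  if (!preprocessed) {
    session <- preprocess_session(session, keypoints = "head",
                                  likelihood_threshold = likelihood_threshold,
                                  jump_quantile = jump_quantile)
  }
  kin <- track_kinematics(session$tracks, keypoint = "head",
                          window = window, site = site)
  radii <- distinct(kin, .data$fish_id) |>
    mutate(surface_radius_used = surface_radius)
  if (!is.null(overrides) && "surface_radius" %in% names(overrides)) {
    radii <- radii |>
      left_join(select(overrides, "fish_id", "surface_radius"),
                by = "fish_id") |>
      mutate(surface_radius_used = dplyr::coalesce(.data$surface_radius,
                                                   .data$surface_radius_used)) |>
      select(-"surface_radius")
  }
  bursts <- velocity_bursts(kin, fraction = burst_fraction,
                            overrides = overrides)
  thr <- attr(bursts, "thresholds")
  kin <- left_join(kin, radii, by = "fish_id")
  per_trial <- kin |>
    group_by(.data$fish_id, .data$trial) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(
      at_surface_start = {
        def <- which(!is.na(.data$dist_food))
        length(def) > 0L &&
          .data$dist_food[def[1]] <= .data$surface_radius_used[1]
      },
      arrivals = {
        at <- !is.na(.data$dist_food) &
          .data$dist_food <= .data$surface_radius_used[1]
        list(.data$t[true_runs(at)$start])
      },
      .groups = "drop"
    )
  res <- per_trial |>
    left_join(tidyr::nest(bursts, burst_tbl = c("start_s", "end_s")),
              by = c("fish_id", "trial")) |>
    mutate(
      t1 = purrr::pmap_dbl(
        list(.data$burst_tbl, .data$arrivals, .data$at_surface_start),
        function(b, a, s0) first_surface_bound_time(b, a, s0, timing)
      ),
      success = trial_success(.data$t1, timing),
      method = "auto"
    ) |>
    left_join(thr, by = "fish_id") |>
    left_join(radii, by = "fish_id") |>
    select("fish_id", "trial", "t1", "success", "method",
           burst_threshold_used = "burst_threshold",
           "surface_radius_used")
  res
}

#' Per-fish session summary
#'
#' Aggregates per-trial t1 results into the study's per-fish metrics: mean
#' t1 and percent success over the early (trials 1--7) and late (trials
#' 11--17) windows, learning indices for several run lengths, and the
#' eating-based inclusion flag. Percent success uses the full window length
#' (7) as denominator; the number of trials actually contributing is
#' reported alongside.
#'
#' @param t1_tbl Per-trial tibble (`fish_id`, `trial`, `t1`, `success`),
#'   e.g. from [compute_t1()].
#' @param meta Optional metadata with `fish_id`, `trial`, `ate` for the
#'   inclusion rule.
#' @param k Run lengths for the learning index.
#' @param min_eating Minimum number of eating trials for inclusion.
#' @param early_trials,late_trials Trial numbers of the two windows.
#' @return One row per fish with means, percentages, learning indices,
#'   trial counts and `included`.
#' @export
session_summary <- function(t1_tbl, meta = NULL, k = c(2, 3, 4),
                            min_eating = 3, early_trials = 1:7,
                            late_trials = 11:17) {
  win <- function(df, trials) df[df$trial %in% trials & !is.na(df$t1), ]
  out <- t1_tbl |>
    group_by(.data$fish_id) |>
    group_modify(function(df, key) {
      e <- win(df, early_trials); l <- win(df, late_trials)
      li <- vapply(k, function(kk) {
        full <- df$success[order(df$trial)]
        # keep trial numbering: re-expand to 1..max(trial)
        s <- rep(NA, max(df$trial))
        s[df$trial] <- df$success
        learning_index(s, kk)
      }, numeric(1))
      res <- tibble(
        mean_t1_early = if (nrow(e)) mean(e$t1) else NA_real_,
        mean_t1_late = if (nrow(l)) mean(l$t1) else NA_real_,
        pct_success_early = 100 * sum(e$success) / length(early_trials),
        pct_success_late = 100 * sum(l$success) / length(late_trials),
        n_trials_used_early = nrow(e),
        n_trials_used_late = nrow(l)
      )
      for (i in seq_along(k)) res[[paste0("learning_index_k", k[i])]] <- li[i]
      res
    }) |>
    ungroup()
  if (!is.null(meta) && "ate" %in% names(meta)) {
    eating <- meta |>
      group_by(.data$fish_id) |>
      summarise(n_eating = sum(.data$ate, na.rm = TRUE), .groups = "drop")
    out <- out |>
      left_join(eating, by = "fish_id") |>
      mutate(included = .data$n_eating >= min_eating)
  }
  out
}
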