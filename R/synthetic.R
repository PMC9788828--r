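# Synthetic-data generators for every input the pipeline consumes, with
# ground truth attached. All generators are pure functions of
# (configuration, seed).

#' Configuration for the trajectory generator
#'
#' Defaults emulate the behavioural assay: 17 trials per fish at 20 frames/s
#' in an 18 s window recorded at 640x480 px, light at 2 s and food at 9 s.
#' The per-trial true surface-bound latency decays geometrically from ~12 s
#' (first trial, before the light means anything to the fish) to ~3 s (a
#' trained fish launching shortly after light onset), with per-trial jitter.
#'
#' The ascent itself is the decelerating half of a ballistic profile:
#' velocity is maximal at launch and falls linearly to zero at the surface,
#' reached within `ascent_duration_s`. This puts launch-time velocities
#' comfortably in the top quarter of each animal's velocity range.
#'
#' @param n_fish,n_trials Number of fish and trials per fish.
#' @param fps Frames per second.
#' @param trial_len_s Trial length (s).
#' @param tank_w,tank_h Tank image size in pixels.
#' @param light_on_s,food_drop_s Stimulus times (s).
#' @param latency_s Per-trial base latency curve (length `n_trials`).
#' @param latency_jitter_sd Per-trial Gaussian jitter on the latency (s).
#' @param ascent_duration_s Time from launch to surface (s).
#' @param noise_sd Gaussian positional noise on keypoints (px).
#' @param dropout_p Per-frame probability of a likelihood dropout (frame
#'   scored below the 0.999 gating threshold).
#' @param teleport_p Per-frame probability of a jump artifact.
#' @param surface_radius Radius around the food-drop site that counts as
#'   "at the surface" (px).
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A list of class `track_sim_config`.
#' @export
track_sim_config <- function(n_fish = 16, n_trials = 17, fps = 20,
                             trial_len_s = 18, tank_w = 640, tank_h = 480,
                             light_on_s = 2, food_drop_s = 9,
                             latency_s = 3 + 9 * exp(-(seq_len(n_trials) - 1) / 4),
                             latency_jitter_sd = 0.5,
                             ascent_duration_s = 0.9,
                             noise_sd = 2, dropout_p = 0.05,
                             teleport_p = 0.01, surface_radius = 125,
                             seed = 1) {
  stopifnot(length(latency_s) == n_trials,
            all(latency_s >= 0), all(latency_s <= trial_len_s),
            dropout_p >= 0, dropout_p <= 1,
            teleport_p >= 0, teleport_p <= 1)
  if (surface_radius >= tank_h) {
    abort("Impossible geometry: surface radius exceeds tank height.")
  }
  structure(as.list(environment()), class = "track_sim_config")
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# One trial's noise-free head trajectory: bottom wander, decelerating
# ascent from the launch point to just under the food-drop site, then
# surface hover.
sim_trial_path <- function(cfg, t0, food) {
  n <- cfg$trial_len_s * cfg$fps
  tt <- (seq_len(n) - 1) / cfg$fps
  Tasc <- cfg$ascent_duration_s
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, 0.25 * cfg$tank_w, 0.75 * cfg$tank_w)
  y[1] <- cfg$tank_h - 60
  wander <- which(tt < t0)
  if (length(wander) > 1L) {
    x[wander] <- clamp(x[1] + cumsum(c(0, stats::rnorm(length(wander) - 1, 0, 3))),
                       20, cfg$tank_w - 20)
    y[wander] <- clamp(y[1] + cumsum(c(0, stats::rnorm(length(wander) - 1, 0, 1))),
                       cfg$tank_h - 110, cfg$tank_h - 25)
  } else if (length(wander) == 1L) {
    x[wander] <- x[1]; y[wander] <- y[1]
  }
  i0 <- length(wander)
  if (i0 < n) {
    xs <- if (i0 >= 1L) x[i0] else x[1]
    ys <- if (i0 >= 1L) y[i0] else y[1]
    target <- c(food[1] + stats::rnorm(1, 0, 10), food[2] + 25)
    rest <- (i0 + 1L):n
    u <- clamp((tt[rest] - t0) / Tasc, 0, 1)
    s <- 1 - (1 - u)^2                     # decelerating half-profile
    x[rest] <- xs + s * (target[1] - xs)
    y[rest] <- ys + s * (target[2] - ys)
    hover <- rest[u >= 1]
    if (length(hover) > 1L) {
      x[hover] <- clamp(x[hover] + cumsum(stats::rnorm(length(hover), 0, 1.5)),
                        target[1] - 40, target[1] + 40)
      y[hover] <- clamp(y[hover] + cumsum(stats::rnorm(length(hover), 0, 1)),
                        target[2] - 20, target[2] + 30)
    }
  }
  tibble(frame = seq_len(n) - 1L, t = tt, x = x, y = y)
}

#' Simulate a session of pose tracks with ground truth
#'
#' Generates, per fish and trial, a noise-free trajectory (bottom wander,
#' ballistic ascent at the true latency, surface hover), adds Gaussian
#' positional noise, injects likelihood dropouts (likelihood drawn below
#' the 0.999 gate) and teleport artifacts (displacement of 10x the 99th
#' percentile of normal step lengths), and packages the result as the same
#' session object the readers produce, alongside the generator truth.
#'
#' @param config A [track_sim_config()].
#' @return A list of class `killicog_sim`: `session` (a
#'   `killicog_session`), `truth` (per-trial realised latency, arrival
#'   time, injected dropout/teleport frames), `clean` (noise-free head
#'   positions) and `config`.
#' @export
simulate_tracks <- function(config = track_sim_config()) {
  stopifnot(inherits(config, "track_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  food <- c(cfg$tank_w / 2, 20)
  light <- c(cfg$tank_w / 2 + 60, 15)
  n <- cfg$trial_len_s * cfg$fps
  fish_ids <- sprintf("f%02d", seq_len(cfg$n_fish))
  grid <- tidyr::expand_grid(fish_id = fish_ids,
                             trial = seq_len(cfg$n_trials))
  sims <- purrr::pmap(grid, function(fish_id, trial) {
    t0 <- clamp(cfg$latency_s[trial] +
                  stats::rnorm(1, 0, cfg$latency_jitter_sd),
                1, cfg$trial_len_s)
    path <- sim_trial_path(cfg, t0, food)
    dist <- sqrt((path$x - food[1])^2 + (path$y - food[2])^2)
    arr <- which(dist <= cfg$surface_radius)
    list(fish_id = fish_id, trial = trial, latency = t0, path = path,
         arrival = if (length(arr)) path$t[arr[1]] else NA_real_)
  })
  clean <- purrr::map(sims, function(s) {
    mutate(s$path, fish_id = s$fish_id, trial = s$trial, .before = 1L)
  }) |> list_rbind()

  noisy_x <- clean$x + stats::rnorm(nrow(clean), 0, cfg$noise_sd)
  noisy_y <- clean$y + stats::rnorm(nrow(clean), 0, cfg$noise_sd)
  # teleport magnitude calibrated to the session's normal step lengths
  step <- sqrt(diff(noisy_x)^2 + diff(noisy_y)^2)
  step <- step[diff(clean$frame) == 1L]
  tp_mag <- 10 * pctl(step, 0.99)
  tp <- stats::runif(nrow(clean)) < cfg$teleport_p
  theta <- stats::runif(sum(tp), 0, 2 * pi)
  noisy_x[tp] <- noisy_x[tp] + tp_mag * cos(theta)
  noisy_y[tp] <- noisy_y[tp] + tp_mag * sin(theta)
  drop <- stats::runif(nrow(clean)) < cfg$dropout_p
  lik <- ifelse(drop, stats::runif(nrow(clean), 0, 0.999),
                stats::runif(nrow(clean), 0.999, 1))

  head_kp <- clean |>
    select("fish_id", "trial", "frame") |>
    mutate(keypoint = "head", x = noisy_x, y = noisy_y, likelihood = lik)
  tail_kp <- head_kp |>
    mutate(keypoint = "tail",
           x = .data$x + stats::rnorm(dplyr::n(), 0, cfg$noise_sd),
           y = .data$y + 25 + stats::rnorm(dplyr::n(), 0, cfg$noise_sd),
           likelihood = stats::runif(dplyr::n(), 0.999, 1))
  food_kp <- clean |>
    select("fish_id", "trial", "frame") |>
    mutate(keypoint = "food_drop",
           x = food[1] + stats::rnorm(dplyr::n(), 0, 1),
           y = food[2] + stats::rnorm(dplyr::n(), 0, 1),
           likelihood = stats::runif(dplyr::n(), 0.95, 1))
  light_kp <- clean |>
    select("fish_id", "trial", "frame") |>
    mutate(keypoint = "red_light",
           x = light[1], y = light[2],
           likelihood = stats::runif(dplyr::n(), 0.999, 1))
  tracks <- bind_rows(head_kp, tail_kp, food_kp, light_kp) |>
    arrange(.data$fish_id, .data$trial, .data$keypoint, .data$frame)
  attr(tracks, "fps") <- cfg$fps

  inj <- clean |>
    select("fish_id", "trial", "frame") |>
    mutate(drop = drop, tp = tp) |>
    group_by(.data$fish_id, .data$trial) |>
    summarise(n_dropout = sum(.data$drop), n_teleport = sum(.data$tp),
              dropout_frames = list(.data$frame[.data$drop]),
              teleport_frames = list(.data$frame[.data$tp]),
              .groups = "drop")
  truth <- purrr::map(sims, function(s) {
    tibble(fish_id = s$fish_id, trial = s$trial, latency_s = s$latency,
           arrival_s = s$arrival)
  }) |> list_rbind() |>
    left_join(inj, by = c("fish_id", "trial"))

  meta <- grid |>
    mutate(sex = ifelse(match(.data$fish_id, fish_ids) %% 2 == 1, "M", "F"),
           age_days = 60L,
           ate = TRUE)
  structure(
    list(session = new_session(tracks, meta), truth = truth,
         clean = clean, config = cfg),
    class = "killicog_sim"
  )
}

#' @export
print.killicog_sim <- function(x, ...) {
  cat("<killicog_sim> ", x$config$n_fish, " fish x ", x$config$n_trials,
      " trials, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Derive manual per-second score sheets from a simulated session
#'
#' Emulates second-by-second human scoring of the noise-free trajectories:
#' `upward` flags a net displacement toward the surface larger than
#' `upward_threshold_px` within the second, `at_surface` flags any frame
#' within the surface radius of the food-drop site, and `eating` flags
#' surface seconds after food arrival. For trials listed in
#' `pause_trials`, a spurious pre-ascent (one upward second followed by a
#' one-second pause) is inserted ahead of the true launch to exercise the
#' run-restart rule; the expected manual t1 is unchanged.
#'
#' @param sim A `killicog_sim` from [simulate_tracks()].
#' @param pause_trials Optional tibble (`fish_id`, `trial`).
#' @param upward_threshold_px Minimum per-second upward displacement a
#'   scorer would call an ascent.
#' @return A tibble `fish_id`, `trial`, `second`, `upward`, `at_surface`,
#'   `eating`.
#' @export
simulate_manual_scores <- function(sim, pause_trials = NULL,
                                   upward_threshold_px = 20) {
  stopifnot(inherits(sim, "killicog_sim"))
  cfg <- sim$config
  food <- c(cfg$tank_w / 2, 20)
  scores <- sim$clean |>
    mutate(second = floor(.data$t),
           dist = sqrt((.data$x - food[1])^2 + (.data$y - food[2])^2)) |>
    group_by(.data$fish_id, .data$trial, .data$second) |>
    summarise(
      upward = as.integer(dplyr::first(.data$y) - dplyr::last(.data$y) >
                            upward_threshold_px),
      at_surface = as.integer(any(.data$dist <= cfg$surface_radius)),
      .groups = "drop"
    ) |>
    mutate(eating = as.integer(.data$at_surface == 1L &
                                 .data$second >= cfg$food_drop_s))
  if (!is.null(pause_trials) && nrow(pause_trials)) {
    scores <- scores |>
      group_by(.data$fish_id, .data$trial) |>
      group_modify(function(df, key) {
        hit <- nrow(semi_join(pause_trials, key,
                              by = intersect(names(key),
                                             names(pause_trials)))) > 0
        if (hit) {
          first_up <- which(df$upward == 1L)
          if (length(first_up) && first_up[1] >= 3L) {
            df$upward[first_up[1] - 2L] <- 1L  # spurious pre-ascent
            df$upward[first_up[1] - 1L] <- 0L  # the pause
          }
        }
        df
      }) |>
      ungroup()
  }
  scores
}

#' Simulate a feeder scheduled/confirmed log
#'
#' Each feeder-day schedules `scheduled_per_day` feedings; each scheduled
#' feeding is independently missed with probability `miss_p`.
#'
#' @param n_feeders,days Grid of feeders and days.
#' @param scheduled_per_day Feedings scheduled per day (default 7).
#' @param miss_p Per-feeding miss probability.
#' @param seed Integer seed.
#' @return A tibble `feeder`, `day`, `scheduled`, `confirmed`.
#' @export
simulate_feeder_log <- function(n_feeders = 41, days = 30,
                                scheduled_per_day = 7, miss_p = 0.019,
                                seed = 1) {
  stopifnot(miss_p >= 0, miss_p <= 1)
  set.seed(seed)
  grid <- tidyr::expand_grid(feeder = seq_len(n_feeders),
                             day = seq_len(days))
  grid |>
    mutate(scheduled = scheduled_per_day,
           confirmed = scheduled_per_day -
             stats::rbinom(dplyr::n(), scheduled_per_day, miss_p))
}

#' Simulate right-censored Gompertz lifespans
#'
#' Inverse-CDF sampling of the Gompertz law
#' `t = (1/b) ln(1 - (b/a) ln U)` (exponential when `b = 0`), with
#' independent censoring marks.
#'
#' @param n Number of animals.
#' @param rate,shape Gompertz parameters a (> 0) and b (>= 0), per time
#'   unit.
#' @param censor_p Probability an animal is censored (observed = 0).
#' @param time_unit Days per time unit (lifespans are reported in days).
#' @param sex,diet,cohort Optional label columns.
#' @param seed Integer seed.
#' @return A tibble `lifespan_days`, `observed` (+ labels).
#' @export
simulate_lifespans <- function(n, rate = 0.05, shape = 0.3, censor_p = 0,
                               time_unit = 1, sex = NA, diet = NA,
                               cohort = NA, seed = 1) {
  stopifnot(rate > 0, shape >= 0, censor_p >= 0, censor_p < 1)
  set.seed(seed)
  u <- stats::runif(n)
  t <- if (shape == 0) -log(u) / rate else
    (1 / shape) * log(1 - (shape / rate) * log(u))
  tibble(
    lifespan_days = t * time_unit,
    observed = 1L - stats::rbinom(n, 1, censor_p),
    sex = sex, diet = diet, cohort = cohort
  )
}

#' Simulate paired sex/diet differential-expression tables
#'
#' Gene-level mean expression is log-normal; each gene is assigned to the
#' sex-significant/diet-significant cells of the 2x2 joint distribution
#' with `P(both) = sex_frac * diet_frac * enrichment_lift`
#' (`enrichment_lift = 1` plants independence). Adjusted p-values are drawn
#' below the 0.05 threshold for significant genes and above it otherwise;
#' a fraction of genes get a missing adjusted p per table, as DE pipelines
#' produce for low-count genes.
#'
#' @param n_genes Universe size.
#' @param sex_frac,diet_frac Marginal fractions of sex and diet DEGs.
#' @param enrichment_lift Multiplicative dependence between the two DEG
#'   statuses (1 = independent); inconsistent joints (negative cell
#'   probabilities) are an error.
#' @param na_frac Fraction of genes with missing `padj` in each table.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param expr_dependent If `TRUE`, diet DEGs are drawn preferentially from
#'   high-expression genes, stressing the expression-matching step.
#' @param seed Integer seed.
#' @return A list with `sex` and `diet` DE tibbles (`gene_id`, `log2fc`,
#'   `p`, `padj`, `mean_expr`) and `truth` (per-gene planted statuses).
#' @export
simulate_deg_tables <- function(n_genes = 10000, sex_frac = 0.15,
                                diet_frac = 0.02, enrichment_lift = 1,
                                na_frac = 0.02, expr_meanlog = 3,
                                expr_sdlog = 1.5, expr_dependent = FALSE,
                                seed = 1) {
  stopifnot(sex_frac >= 0, sex_frac <= 1, diet_frac >= 0, diet_frac <= 1)
  p11 <- sex_frac * diet_frac * enrichment_lift
  p10 <- sex_frac - p11
  p01 <- diet_frac - p11
  p00 <- 1 - p11 - p10 - p01
  if (any(c(p11, p10, p01, p00) < -1e-12)) {
    abort("Inconsistent joint specification: a cell probability is negative.")
  }
  set.seed(seed)
  expr <- stats::rlnorm(n_genes, expr_meanlog, expr_sdlog)
  # differential expression is only callable with adequate counts: planted
  # DEGs live in the central expression band (within 2 SD of the log-mean),
  # as independent filtering would enforce in a real DE table; this also
  # keeps expression-matched control pools populated at tight tolerances
  elig <- abs(log(expr) - expr_meanlog) <= 2 * expr_sdlog
  p_elig <- mean(elig)
  if (diet_frac / p_elig > 1 || sex_frac / p_elig > 1) {
    abort("Inconsistent joint specification: DEG fraction too large for the callable expression band.")
  }
  if (expr_dependent) {
    w <- (rank(expr) / n_genes)^2 * elig
    diet_sig <- logical(n_genes)
    n_diet <- round(diet_frac * n_genes)
    if (n_diet > 0) {
      diet_sig[sample.int(n_genes, n_diet, prob = w)] <- TRUE
    }
  } else {
    diet_sig <- elig & stats::runif(n_genes) < diet_frac / p_elig
  }
  # sex status is assigned conditionally on the callable band so that
  # enrichment_lift = 1 gives exact conditional independence of the two
  # DEG statuses among callable genes (the meaningful null for the
  # expression-matched bootstrap), while the overall sex marginal stays
  # sex_frac
  p_sex_given_diet <- min(enrichment_lift * sex_frac / p_elig, 1)
  p11_eff <- diet_frac * p_sex_given_diet
  p_not_diet_elig <- max(p_elig - diet_frac, 0)
  p_sex_given_not <- if (p_not_diet_elig > 0) {
    (sex_frac - p11_eff) / p_not_diet_elig
  } else 0
  if (p_sex_given_not < 0 || p_sex_given_not > 1) {
    abort("Inconsistent joint specification: conditional sex probability outside [0,1].")
  }
  sex_sig <- ifelse(diet_sig,
                    stats::runif(n_genes) < p_sex_given_diet,
                    elig & stats::runif(n_genes) < p_sex_given_not)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  make_tbl <- function(sig) {
    padj <- ifelse(sig, stats::runif(n_genes, 0, 0.049),
                   stats::runif(n_genes, 0.05, 1))
    padj[sample.int(n_genes, round(na_frac * n_genes))] <- NA_real_
    tibble(
      gene_id = gene_id,
      log2fc = stats::rnorm(n_genes, 0, 0.5) + ifelse(sig, sign(stats::rnorm(n_genes)) * 2, 0),
      p = padj * 0.5,
      padj = padj,
      mean_expr = expr
    )
  }
  list(
    sex = make_tbl(sex_sig),
    diet = make_tbl(diet_sig),
    truth = tibble(gene_id = gene_id, sex_sig = sex_sig,
                   diet_sig = diet_sig, mean_expr = expr)
  )
}
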