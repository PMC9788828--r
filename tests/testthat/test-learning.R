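make_fd_track <- function(trial, coords, lik) {
  tibble::tibble(fish_id = "f01", trial = trial,
                 frame = seq_along(lik) - 1L, keypoint = "food_drop",
                 x = coords[, 1], y = coords[, 2], likelihood = lik)
}

test_that("food-drop localization averages per-video argmax coordinates", {
  t1 <- make_fd_track(1, cbind(c(100, 100, 50), c(10, 10, 90)),
                      c(0.2, 0.9, 0.1))
  expect_equal(locate_food_drop(t1)[c("x", "y")],
               tibble::tibble(x = 100, y = 10))

  t2 <- make_fd_track(2, cbind(c(102, 90), c(12, 80)), c(0.95, 0.3))
  both <- dplyr::bind_rows(t1, t2)
  res <- locate_food_drop(both)
  expect_equal(c(res$x, res$y), c(101, 11))
  expect_equal(res$n_videos_used, 2L)

  t3 <- make_fd_track(3, cbind(c(7, 7), c(7, 7)), c(0, 0))
  res2 <- locate_food_drop(dplyr::bind_rows(t1, t2, t3))
  expect_equal(res2$n_videos_used, 2L)             # dead video excluded
  expect_error(locate_food_drop(t3), "zero")
})

test_that("surface arrivals collapse contiguous runs to their first frame", {
  d <- rep(1000, 200)
  expect_equal(nrow(surface_arrivals(make_kin(dist = d), 125)), 0L)

  d2 <- rep(1000, 200); d2[111:131] <- 100        # frames 110-130 (0-based)
  arr <- surface_arrivals(make_kin(dist = d2), 125)
  expect_equal(arr$arrival_s, 5.5)

  d3 <- rep(1000, 200); d3[1] <- 50
  expect_equal(surface_arrivals(make_kin(dist = d3), 125)$arrival_s[1], 0)
})

test_that("burst threshold is a range fraction and runs are maximal", {
  v <- rep(0, 200); v[101:121] <- 8                # frames 100-120
  kin <- make_kin(v = v)
  b <- velocity_bursts(kin, 0.75)
  thr <- attr(b, "thresholds")
  expect_equal(thr$burst_threshold, 6)             # 0 + 0.75 * 8
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start_s, b$end_s), c(5.0, 6.0))

  # a trial with nothing above threshold contributes no bursts
  kin2 <- dplyr::bind_rows(make_kin(trial = 1, v = v),
                           make_kin(trial = 2, v = rep(1, 200)))
  b2 <- velocity_bursts(kin2, 0.75)
  expect_true(all(b2$trial == 1))
  expect_error(velocity_bursts(make_kin(v = rep(NA_real_, 10))), "Empty")
})

test_that("t1 edge rules are applied in order", {
  timing <- trial_timing()
  no_bursts <- tibble::tibble(start_s = numeric(), end_s = numeric())
  expect_equal(first_surface_bound_time(no_bursts, 3.2, TRUE, timing), 0)
  expect_equal(first_surface_bound_time(no_bursts, numeric(0), FALSE,
                                        timing), 18)
  one <- tibble::tibble(start_s = 4.0, end_s = 5.2)
  expect_equal(first_surface_bound_time(one, 5.5, FALSE, timing), 4.0)
  expect_equal(first_surface_bound_time(no_bursts, 5.5, FALSE, timing), 5.5)
  # arrival inside a burst wins over a nearer-by-gap earlier burst
  two <- tibble::tibble(start_s = c(2.0, 5.4), end_s = c(2.5, 6.0))
  expect_equal(first_surface_bound_time(two, 5.5, FALSE, timing), 5.4)
  # ties go to the earlier burst
  tie <- tibble::tibble(start_s = c(3.0, 6.0), end_s = c(4.0, 7.0))
  expect_equal(first_surface_bound_time(tie, 5.0, FALSE, timing), 3.0)
})

test_that("success is the closed [light, food] window", {
  expect_true(trial_success(2))
  expect_true(trial_success(9))
  expect_false(trial_success(9.5))
  expect_false(trial_success(0))
  expect_false(trial_success(1.95))
  # success is true exactly on a closed interval
  grid <- seq(0, 18, by = 0.05)
  s <- trial_success(grid)
  expect_equal(range(grid[s]), c(2, 9))
  expect_equal(sum(diff(s) != 0), 2L)
})

test_that("learning index is 1/first trial of a k-run, 0 when absent", {
  expect_equal(learning_index(c(F, F, F, T, T)), 0.25)
  expect_equal(learning_index(rep(TRUE, 17)), 1)
  expect_equal(learning_index(rep(c(TRUE, FALSE), 8), k = 2), 0)
  expect_equal(learning_index(logical(0)), 0)
  # antitone in k for random sequences
  set.seed(8)
  for (i in 1:200) {
    s <- runif(sample(3:12, 1)) < 0.5
    li <- vapply(1:4, function(k) learning_index(s, k), numeric(1))
    expect_true(all(diff(li) <= 1e-12))
  }
})

make_sheet <- function(upward, surface, n = 18) {
  tibble::tibble(second = 0:(n - 1),
                 upward = as.integer(0:(n - 1) %in% upward),
                 at_surface = as.integer(0:(n - 1) %in% surface))
}

test_that("manual t1 backtracks through the unbroken ascent", {
  expect_equal(manual_t1(make_sheet(4:7, 7)), 4)
  # pause at second 5 restarts the run: report the post-pause ascent
  expect_equal(manual_t1(make_sheet(c(3, 4, 6, 7), 7)), 6)
  expect_equal(manual_t1(make_sheet(integer(0), integer(0))), 18)
  # surface reached without any scored ascent second
  expect_equal(manual_t1(make_sheet(integer(0), 9)), 9)
})

test_that("session summaries honour windows, denominators and eating rule", {
  t1_tbl <- tibble::tibble(
    fish_id = "f01", trial = 1:17,
    t1 = c(10, 10, 3, 3, 3, 10, NA, 12, 12, 12, 4, 4, 4, 4, 10, 10, 10),
    success = trial_success(t1), method = "auto"
  )
  s <- session_summary(t1_tbl)
  expect_equal(s$n_trials_used_early, 6L)          # trial 7 missing
  expect_equal(s$mean_t1_early, mean(c(10, 10, 3, 3, 3, 10)))
  expect_equal(s$pct_success_early, 100 * 3 / 7)
  expect_equal(s$pct_success_late, 100 * 4 / 7)
  expect_equal(s$learning_index_k2, 1 / 3)
  expect_equal(s$learning_index_k3, 1 / 3)
  expect_equal(s$learning_index_k4, 1 / 11)

  all_s <- dplyr::mutate(t1_tbl, t1 = 5, success = TRUE)
  s2 <- session_summary(all_s)
  expect_equal(s2$pct_success_early, 100)
  expect_equal(s2$pct_success_late, 100)

  meta <- tibble::tibble(fish_id = "f01", trial = 1:17,
                         ate = c(1, 1, rep(0, 15)))
  s3 <- session_summary(t1_tbl, meta)
  expect_false(s3$included)                        # ate in only 2 trials
})

test_that("auto t1 recovers generator truth on noisy sessions", {
  hits <- 0L; total <- 0L
  for (s in 1:2) {
    sim <- simulate_tracks(track_sim_config(n_fish = 6, seed = s))
    t1 <- compute_t1(sim$session)
    m <- dplyr::left_join(t1, sim$truth, by = c("fish_id", "trial"))
    hits <- hits + sum(abs(m$t1 - m$latency_s) <= 0.25)
    total <- total + nrow(m)
  }
  expect_gte(hits / total, 0.95)
})

test_that("auto and manual t1 agree on synthetic sessions", {
  sim <- simulate_tracks(track_sim_config(n_fish = 6, seed = 21))
  auto <- compute_t1(sim$session)
  scores <- simulate_manual_scores(sim)
  man <- scores |>
    dplyr::group_by(fish_id, trial) |>
    dplyr::summarise(t1_manual = manual_t1(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  m <- dplyr::inner_join(auto, man, by = c("fish_id", "trial"))
  expect_gte(pearson_r(m$t1, m$t1_manual), 0.9)
})

test_that("per-animal overrides are honoured and logged", {
  sim <- simulate_tracks(track_sim_config(n_fish = 2, seed = 9))
  ov <- tibble::tibble(fish_id = "f01", burst_fraction = 0.6,
                       surface_radius = 140)
  t1 <- compute_t1(sim$session, overrides = ov)
  expect_equal(unique(t1$surface_radius_used[t1$fish_id == "f01"]), 140)
  expect_equal(unique(t1$surface_radius_used[t1$fish_id == "f02"]), 125)
  thr_default <- compute_t1(sim$session)
  f1_def <- unique(thr_default$burst_threshold_used[thr_default$fish_id == "f01"])
  f1_ov <- unique(t1$burst_threshold_used[t1$fish_id == "f01"])
  expect_lt(f1_ov, f1_def)                         # lower fraction, lower bar
})
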