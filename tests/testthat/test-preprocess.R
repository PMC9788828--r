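test_that("likelihood gating masks coordinates but keeps likelihoods", {
  lik <- c(1, 1, 0.9985, 0.5, 1, 0.99, 1, 1, 1, 1)
  tr <- make_track(10, likelihood = lik)
  out <- likelihood_gate(tr, "head", 0.999)
  expect_equal(sum(is.na(out$x)), 3L)            # direct count oracle
  expect_true(is.na(out$x[3]))                    # 0.9985 < 0.999
  expect_equal(out$likelihood, lik)
  rep_tbl <- filter_report(out)
  expect_equal(rep_tbl$n, 3L)

  clean <- likelihood_gate(make_track(10), "head", 0.999)
  expect_equal(filter_report(clean)$n, 0L)
  expect_error(likelihood_gate(tr, "fin"), "Unknown keypoint")
})

test_that("jump filter flags exactly the injected teleport", {
  # track A: stationary (zero distances); track B: uniform 2 px steps with
  # a 500 px teleport. The pooled 95th percentile lands on the tied 2 px
  # steps, which must not be flagged; only the teleport's two distances are
  # strictly above it.
  n <- 60
  xb <- 100 + 2 * (0:(n - 1))
  xb[30] <- xb[30] + 500
  tracks <- dplyr::bind_rows(
    dplyr::mutate(make_track(n), fish_id = "a", trial = 1L),
    dplyr::mutate(make_track(n, x = xb, y = rep(100, n)),
                  fish_id = "b", trial = 1L)
  )
  attr(tracks, "fps") <- 20
  out <- jump_filter(tracks, "head", 0.05)
  b <- dplyr::filter(out, fish_id == "b")
  a <- dplyr::filter(out, fish_id == "a")
  expect_true(all(!is.na(a$x)))                   # stationary: no anomalies
  # the displaced frame and the frame after it carry the two huge steps
  expect_equal(which(is.na(b$x)), c(30L, 31L))
})

test_that("flagged distances match the sort-and-count quantile oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- 101
    x <- cumsum(rnorm(n, 0, 3)); y <- cumsum(rnorm(n, 0, 3))
    tr <- make_track(n, x = x, y = y)
    d <- sqrt(diff(x)^2 + diff(y)^2)             # 100 pooled distances
    thr <- quantile(d, 0.95, type = 7, names = FALSE)
    expected_masked <- which(d > thr) + 1L       # second frame of the pair
    out <- jump_filter(tr, "head", 0.05)
    expect_equal(which(is.na(out$x)), expected_masked)
    expect_lte(length(expected_masked), ceiling(0.05 * length(d)))
  }
})

test_that("jump filter compares consecutive observations across gated gaps", {
  # a teleported frame right after a gated frame must still be caught
  n <- 40
  x <- rep(100, n); y <- rep(100, n)
  x[20] <- 600                                    # rogue position
  lik <- rep(1, n); lik[19] <- 0.5                # frame before it is gated
  tr <- make_track(n, x = x, y = y, likelihood = lik)
  out <- tr |> likelihood_gate("head") |> jump_filter("head")
  expect_true(is.na(out$x[20]))
})

test_that("gated frames are excluded from the pooled distance distribution", {
  # a rogue position only produces huge steps if the gated frame were
  # (wrongly) kept in the distance pool
  n <- 50
  x <- rep(100, n); y <- rep(0, n)
  x[25] <- 1000; lik <- rep(1, n); lik[25] <- 0.1
  tr <- make_track(n, x = x, y = y, likelihood = lik)
  out <- tr |> likelihood_gate("head") |> jump_filter("head")
  expect_equal(which(is.na(out$x)), 25L)          # only the gated frame
  # two-stage comparison: skipping the gate leaves the rogue point in the
  # pool and its neighbours get masked as anomalies
  out2 <- jump_filter(tr, "head")
  expect_true(all(c(25L, 26L) %in% which(is.na(out2$x))))
})

test_that("spline fill reproduces low-degree polynomials and never extrapolates", {
  n <- 30
  y_line <- seq_len(n) + 0
  tr <- make_track(n, x = y_line, y = y_line)
  tr$x[15] <- NA; tr$y[15] <- NA
  out <- spline_interpolate(tr, "head")
  expect_equal(out$x[15], 15, tolerance = 1e-9)  # on the line

  tr2 <- make_track(n, x = y_line, y = y_line)
  tr2$x[1:5] <- NA; tr2$y[1:5] <- NA
  out2 <- spline_interpolate(tr2, "head")
  expect_true(all(is.na(out2$x[1:5])))            # leading run stays missing
  rep2 <- filter_report(out2)
  expect_equal(rep2$n[rep2$stage == "residual_missing"], 5L)
})

test_that("spline fill matches the tridiagonal natural-spline oracle", {
  t <- 0:19
  y <- (t - 8)^3 / 50
  gap <- 9:11
  tr <- make_track(20, x = y, y = y + 2)
  tr$x[gap] <- NA; tr$y[gap] <- NA
  out <- spline_interpolate(tr, "head")
  obs <- setdiff(seq_len(20), gap)
  expected <- oracle_natural_spline(t[obs], y[obs], t[gap])
  expect_equal(out$x[gap], expected, tolerance = 1e-8)
  # idempotence
  again <- spline_interpolate(out, "head")
  expect_equal(again$x, out$x)
  expect_equal(again$y, out$y)
})

test_that("degenerate tracks pass through the spline with a warning", {
  tr <- make_track(6)
  tr$x[2:6] <- NA; tr$y[2:6] <- NA               # only one observation
  expect_warning(out <- spline_interpolate(tr, "head"), "fewer than 4")
  expect_equal(sum(is.na(out$x)), 5L)
})

test_that("the full prefilter is the identity on clean tracks", {
  tr <- dplyr::mutate(make_track(60, x = sin(1:60), y = cos(1:60)),
                      fish_id = "a", trial = 1L)
  tr2 <- dplyr::mutate(make_track(60, x = cos(1:60), y = sin(1:60)),
                       fish_id = "a", trial = 2L)
  tracks <- dplyr::bind_rows(tr, tr2)
  attr(tracks, "fps") <- 20
  out <- preprocess_tracks(tracks)
  expect_equal(out$x, tracks$x)
  expect_equal(out$y, tracks$y)
  rep_tbl <- preprocess_report(out)
  expect_true(all(rep_tbl$n_gated == 0))
  expect_true(all(rep_tbl$n_interpolated == 0))
})

test_that("prefilter counts tie out against generator ground truth", {
  sim <- simulate_tracks(track_sim_config(n_fish = 3, seed = 11))
  ses <- preprocess_session(sim$session)
  rep_tbl <- ses$report |>
    dplyr::left_join(sim$truth, by = c("fish_id", "trial"))
  # every dropout frame is gated, and nothing else is
  expect_equal(rep_tbl$n_gated, rep_tbl$n_dropout)
  # teleports are caught: anomaly masking is at least as large as the
  # number of injected teleports that were not already gated as dropouts
  tp <- tidyr::unnest(sim$truth[c("fish_id", "trial", "teleport_frames")],
                      "teleport_frames")
  if (nrow(tp)) expect_gte(sum(rep_tbl$n_anomalies), nrow(tp) * 0.9)
  # conservation per track: filled + residual = gated + anomalies
  expect_equal(rep_tbl$n_interpolated + rep_tbl$n_residual_missing,
               rep_tbl$n_gated + rep_tbl$n_anomalies)
})

test_that("stages are monotone: later stages never unmask earlier ones", {
  sim <- simulate_tracks(track_sim_config(n_fish = 2, seed = 3))
  g <- likelihood_gate(sim$session$tracks, "head")
  gj <- jump_filter(g, "head")
  na_g <- is.na(dplyr::filter(g, keypoint == "head")$x)
  na_gj <- is.na(dplyr::filter(gj, keypoint == "head")$x)
  expect_true(all(na_gj[na_g]))
})
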