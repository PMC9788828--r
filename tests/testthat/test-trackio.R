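test_that("write/read round trip is the identity to 6 decimals", {
  set.seed(7)
  n <- 360
  tr <- dplyr::bind_rows(
    tibble::tibble(frame = 0:(n - 1), keypoint = "head",
                   x = runif(n, 0, 640), y = runif(n, 0, 480),
                   likelihood = runif(n)),
    tibble::tibble(frame = 0:(n - 1), keypoint = "food_drop",
                   x = 320 + rnorm(n), y = 20 + rnorm(n),
                   likelihood = runif(n))
  )
  tr$x[c(5, 50)] <- NA; tr$y[c(5, 50)] <- NA   # missing cells survive
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(tr, path)
  back <- read_pose_csv(path, fps = 20)
  expect_equal(attr(back, "n_frames"), n)
  expect_setequal(unique(back$keypoint), c("head", "food_drop"))
  merged <- dplyr::inner_join(tr, back, by = c("frame", "keypoint"))
  expect_equal(nrow(merged), nrow(tr))
  expect_equal(merged$x.y, merged$x.x, tolerance = 1e-6)
  expect_equal(merged$y.y, merged$y.x, tolerance = 1e-6)
  expect_equal(merged$likelihood.y, merged$likelihood.x, tolerance = 1e-6)
})

test_that("a minimal two-frame file parses and frame counts are preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_lines(path,
                  parts = rep(c("head", "food_drop"), each = 3),
                  coords = rep(c("x", "y", "likelihood"), 2),
                  body = c("0,1.5,2.5,0.9991,100,20,1",
                           "1,1.6,2.4,0.9999,100,20,1"))
  tr <- read_pose_csv(path)
  expect_equal(attr(tr, "n_frames"), 2L)
  expect_equal(dplyr::n_distinct(tr$keypoint), 2L)
  expect_equal(nrow(tr), 4L)
})

test_that("snout is aliased to head on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_dlc_lines(path, parts = rep("snout", 3),
                  coords = c("x", "y", "likelihood"),
                  body = "0,1,2,1")
  expect_equal(unique(read_pose_csv(path)$keypoint), "head")
})

test_that("malformed pose files fail with informative errors", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  # coords row lacks likelihood for food_drop
  write_dlc_lines(p1, parts = c(rep("head", 3), "food_drop", "food_drop"),
                  coords = c("x", "y", "likelihood", "x", "y"),
                  body = "0,1,2,1,3,4")
  expect_error(read_pose_csv(p1), "food_drop.*triplet|coords")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,s,s,s", "coords,x,y,likelihood", "0,1,2,1"), p2)
  expect_error(read_pose_csv(p2), "bodyparts")

  p3 <- withr::local_tempfile(fileext = ".csv")
  write_dlc_lines(p3, parts = rep("head", 3),
                  coords = c("x", "y", "likelihood"),
                  body = c("0,1,2,0.5", "1,1,2,1.7"))
  expect_error(read_pose_csv(p3), "frame 1")

  expect_error(read_pose_csv(file.path(tempdir(), "nope.csv")), "No such file")
})

test_that("writing an empty track errors; 360-frame track writes 360 rows", {
  expect_error(write_pose_csv(make_track(0), tempfile()), "empty")
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(make_track(360), path)
  expect_length(readLines(path), 363L)  # 3 header rows + 360 data rows
})

test_that("manual score sheets are validated and re-serialize identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(second = 0:17, upward = 0L, at_surface = 0L)
  readr::write_csv(df, path)
  sheet <- read_manual_scores(path)
  expect_equal(nrow(sheet), 18L)
  expect_true(all(sheet$at_surface == 0))
  expect_length(attr(sheet, "gaps"), 0L)

  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(sheet), path2)
  again <- read_manual_scores(path2)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(sheet))

  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(df, upward = ifelse(second == 3, 2L, 0L)),
                   path3)
  expect_error(read_manual_scores(path3), "0/1")

  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df[-c(5, 9), ], path4)
  expect_equal(attr(read_manual_scores(path4), "gaps"), c(4, 8))
})

write_session_fixture <- function(dir, fish = "01", trials = 1:17) {
  dir.create(dir, showWarnings = FALSE)
  for (k in trials) {
    write_pose_csv(make_track(40, keypoints = c("head", "food_drop")),
                   file.path(dir, sprintf("fish%s_trial%d.csv", fish, k)))
  }
  meta <- tidyr::expand_grid(fish_id = fish, trial = 1:17) |>
    dplyr::mutate(sex = "M", age_days = 60, ate = 1)
  meta_path <- file.path(dir, "meta.csv")
  readr::write_csv(meta, meta_path)
  meta_path
}

test_that("a complete session loads with an empty missing-list", {
  dir <- withr::local_tempdir()
  meta_path <- write_session_fixture(dir)
  ses <- load_session(dir, meta_path)
  expect_s3_class(ses, "killicog_session")
  expect_equal(nrow(ses$missing), 0L)
  expect_equal(dplyr::n_distinct(ses$tracks$trial), 17L)
  # multiset of (fish, trial) pairs on disk is preserved
  expect_equal(nrow(dplyr::distinct(ses$tracks, fish_id, trial)), 17L)
})

test_that("an absent trial is reported, not fatal", {
  dir <- withr::local_tempdir()
  meta_path <- write_session_fixture(dir, trials = setdiff(1:17, 7))
  expect_warning(ses <- load_session(dir, meta_path), "no track file")
  expect_equal(ses$missing$trial, 7)
  expect_false(7 %in% ses$tracks$trial)
})

test_that("duplicate metadata rows and uncovered tracks are errors", {
  dir <- withr::local_tempdir()
  meta_path <- write_session_fixture(dir)
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  dup <- file.path(dir, "dup.csv")
  readr::write_csv(dplyr::bind_rows(meta, meta[1, ]), dup)
  expect_error(load_session(dir, dup), "Duplicate")
  short <- file.path(dir, "short.csv")
  readr::write_csv(meta[-1, ], short)
  expect_error(load_session(dir, short), "without metadata")
})
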