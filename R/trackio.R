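# Reading and writing pose tracks, manual score sheets and session metadata.

#' Trial timing constants
#'
#' The behavioural trial runs on a fixed schedule: the red LED (conditioned
#' stimulus) turns on at 2 s, food (unconditioned stimulus) reaches the water
#' surface nominally at 9 s, and analysis windows close at 18 s.
#'
#' @param light_on_s Seconds from recording start to light onset.
#' @param food_drop_s Seconds from recording start to food arrival.
#' @param trial_end_s Length of the analysed trial window in seconds.
#' @return A named list with the three constants, validated for ordering.
#' @export
#' @examples
#' trial_timing()
trial_timing <- function(light_on_s = 2, food_drop_s = 9, trial_end_s = 18) {
  if (!(light_on_s < food_drop_s && food_drop_s < trial_end_s)) {
    abort("Timing must satisfy light_on_s < food_drop_s < trial_end_s.")
  }
  list(light_on_s = light_on_s, food_drop_s = food_drop_s,
       trial_end_s = trial_end_s)
}

#' Read a pose-estimation CSV export (DeepLabCut dialect)
#'
#' The expected file has three header rows -- `scorer`, `bodyparts`,
#' `coords` -- with an `x`, `y`, `likelihood` column triplet per keypoint and
#' the frame index in the first column. Empty coordinate cells become `NA`
#' (the package's only missing marker).
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the recording (stored on the result).
#' @param aliases Named character vector mapping alternative keypoint names
#'   onto canonical ones, e.g. `c(snout = "head")`.
#' @return A tibble of class `pose_track` with columns `frame`, `keypoint`,
#'   `x`, `y`, `likelihood`, one row per frame per keypoint, and attributes
#'   `fps` and `n_frames`.
#' @export
read_pose_csv <- function(path, fps = 20,
                          aliases = c(snout = "head")) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3L) abort("Malformed pose CSV: fewer than three header rows.")
  labels <- c("scorer", "bodyparts", "coords")
  for (i in 1:3) {
    if (!identical(tolower(raw[[1]][i]), labels[i])) {
      abort(paste0("Malformed pose CSV: missing '", labels[i],
                   "' header row (row ", i, ")."))
    }
  }
  parts <- as.character(raw[2, -1])
  coords <- tolower(as.character(raw[3, -1]))
  parts <- ifelse(parts %in% names(aliases), unname(aliases[parts]), parts)
  bad <- !coords %in% c("x", "y", "likelihood")
  if (any(bad)) {
    abort(paste0("Malformed pose CSV: unknown coords label '",
                 coords[bad][1], "'."))
  }
  for (kp in unique(parts)) {
    have <- sort(coords[parts == kp])
    if (!identical(have, c("likelihood", "x", "y"))) {
      abort(paste0("Malformed pose CSV: keypoint '", kp,
                   "' lacks a complete x/y/likelihood triplet ",
                   "(coords row incomplete)."))
    }
  }
  body <- raw[-(1:3), , drop = FALSE]
  n_frames <- nrow(body)
  frame <- as.integer(body[[1]])
  if (n_frames > 1L && any(diff(frame) <= 0L)) {
    abort("Frame index must be strictly increasing.")
  }
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  cols <- lapply(seq_along(parts), function(j) num(body[[j + 1L]]))
  out <- purrr::map(unique(parts), function(kp) {
    idx <- which(parts == kp)
    tibble(
      frame = frame, keypoint = kp,
      x = cols[[idx[coords[idx] == "x"]]],
      y = cols[[idx[coords[idx] == "y"]]],
      likelihood = cols[[idx[coords[idx] == "likelihood"]]]
    )
  }) |> list_rbind()
  bad_lik <- which(!is.na(out$likelihood) &
                     (out$likelihood < 0 | out$likelihood > 1))
  if (length(bad_lik)) {
    abort(paste0("Likelihood outside [0,1] at frame ",
                 out$frame[bad_lik[1]], " (keypoint '",
                 out$keypoint[bad_lik[1]], "')."))
  }
  attr(out, "fps") <- fps
  attr(out, "n_frames") <- n_frames
  class(out) <- c("pose_track", class(out))
  out
}

#' Write a pose track in the three-header-row CSV dialect
#'
#' Inverse of [read_pose_csv()]: numeric fields are written with six decimal
#' places, missing values as empty cells, so a write/read round trip is the
#' identity to 1e-6.
#'
#' @param track A `pose_track` tibble (columns `frame`, `keypoint`, `x`, `y`,
#'   `likelihood`).
#' @param path Output file path.
#' @param scorer Value written in the scorer header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "killicog") {
  stopifnot(all(c("frame", "keypoint", "x", "y", "likelihood") %in%
                  names(track)))
  if (nrow(track) == 0L) abort("Refusing to write an empty track.")
  kps <- unique(track$keypoint)
  frames <- sort(unique(track$frame))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  blocks <- lapply(kps, function(kp) {
    sub <- track[track$keypoint == kp, ]
    sub <- sub[match(frames, sub$frame), ]
    cbind(fmt(sub$x), fmt(sub$y), fmt(sub$likelihood))
  })
  mat <- do.call(cbind, blocks)
  hdr1 <- c("scorer", rep(scorer, ncol(mat)))
  hdr2 <- c("bodyparts", rep(kps, each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(kps)))
  body <- cbind(as.character(frames), mat)
  lines <- c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
             paste(hdr3, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) abort(paste0("Cannot write ", path, ": ",
                                                  conditionMessage(e))))
  invisible(path)
}

#' Read a manual per-second score sheet
#'
#' Manual scoring records, for each second of a trial, whether the fish's
#' midpoint moved toward the water surface (`upward`), whether its snout was
#' at the surface (`at_surface`), and optionally whether it was eating.
#'
#' @param path CSV file with columns `second`, `upward`, `at_surface` and
#'   optionally `eating`.
#' @return A tibble ordered by `second`; missing seconds between the first
#'   and last scored second are reported in the `gaps` attribute.
#' @export
read_manual_scores <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("second", "upward", "at_surface")
  if (!all(need %in% names(df))) {
    abort(paste0("Score sheet must have columns: ",
                 paste(need, collapse = ", ")))
  }
  for (col in intersect(c("upward", "at_surface", "eating"), names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & !v %in% c(0, 1))) {
      abort(paste0("Column '", col, "' must be 0/1; found value ",
                   v[which(!is.na(v) & !v %in% c(0, 1))[1]], "."))
    }
  }
  df <- arrange(df, .data$second)
  full <- seq(min(df$second), max(df$second))
  attr(df, "gaps") <- setdiff(full, df$second)
  df
}

#' Load a session of pose tracks plus trial metadata
#'
#' Track files are discovered in `track_dir` by the pattern
#' `fish<ID>_trial<K>.csv`. Metadata must cover every track found; metadata
#' rows without a matching track are collected in the completeness report
#' (`$missing`) with a warning, not an error, mirroring how individual trial
#' recordings can fail in practice.
#'
#' @param track_dir Directory containing one pose CSV per (fish, trial).
#' @param meta_path CSV with columns `fish_id`, `sex`, `age_days`, `trial`,
#'   `ate` (0/1 eating annotation).
#' @param fps Frames per second, stored on the combined track table.
#' @param aliases Keypoint alias map, see [read_pose_csv()].
#' @return A `killicog_session`: list with `tracks` (long tibble keyed by
#'   `fish_id`, `trial`), `meta`, and `missing` (metadata rows lacking a
#'   track file).
#' @export
load_session <- function(track_dir, meta_path, fps = 20,
                         aliases = c(snout = "head")) {
  files <- list.files(track_dir, pattern = "^fish.+_trial\\d+\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L) abort(paste0("No track files in ", track_dir))
  m <- regmatches(basename(files),
                  regexec("^fish(.+)_trial(\\d+)\\.csv$", basename(files)))
  keys <- tibble(
    fish_id = map_chr(m, 2),
    trial = as.integer(map_chr(m, 3)),
    path = files
  )
  if (anyDuplicated(keys[c("fish_id", "trial")])) {
    abort("Duplicate (fish, trial) track files on disk.")
  }
  meta <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            fish_id = readr::col_character(),
                            .default = readr::col_guess()
                          ))
  need <- c("fish_id", "trial")
  if (!all(need %in% names(meta))) {
    abort("Metadata must have at least fish_id and trial columns.")
  }
  meta$fish_id <- as.character(meta$fish_id)
  if (anyDuplicated(meta[c("fish_id", "trial")])) {
    abort("Duplicate (fish, trial) rows in metadata.")
  }
  no_meta <- anti_join(keys, meta, by = c("fish_id", "trial"))
  if (nrow(no_meta)) {
    abort(paste0("Tracks without metadata, e.g. fish ", no_meta$fish_id[1],
                 " trial ", no_meta$trial[1], "."))
  }
  tracks <- purrr::pmap(keys, function(fish_id, trial, path) {
    tr <- read_pose_csv(path, fps = fps, aliases = aliases)
    mutate(tr, fish_id = fish_id, trial = trial, .before = 1L)
  }) |> list_rbind()
  attr(tracks, "fps") <- fps
  missing <- anti_join(meta, keys, by = c("fish_id", "trial"))
  if (nrow(missing)) {
    warn(paste0(nrow(missing), " metadata row(s) have no track file; ",
                "see $missing."))
  }
  new_session(tracks, meta, missing[c("fish_id", "trial")])
}

new_session <- function(tracks, meta, missing = NULL) {
  structure(
    list(tracks = tracks, meta = meta,
         missing = missing %||% tibble(fish_id = character(),
                                       trial = integer())),
    class = "killicog_session"
  )
}

#' @export
print.killicog_session <- function(x, ...) {
  n_fish <- n_distinct(x$tracks$fish_id)
  n_tr <- nrow(distinct(x$tracks, .data$fish_id, .data$trial))
  cat("<killicog_session> ", n_fish, " fish, ", n_tr, " trials, ",
      "fps = ", track_fps(x$tracks), "\n", sep = "")
  if (nrow(x$missing)) {
    cat("  missing trials:",
        paste0("(", x$missing$fish_id, ", ", x$missing$trial, ")",
               collapse = " "), "\n")
  }
  invisible(x)
}
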