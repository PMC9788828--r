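# Three-step prefilter for pose tracks: likelihood gating, pooled
# jump-anomaly removal, natural cubic-spline interpolation (no
# extrapolation). Stages only ever mask or fill; none un-masks a frame
# masked earlier.

#' Mask keypoint coordinates below a likelihood threshold
#'
#' Frames whose pose-estimation confidence falls below `threshold` have
#' their coordinates set to `NA`; the likelihood values themselves are kept.
#'
#' @param tracks Long track table (`frame`, `keypoint`, `x`, `y`,
#'   `likelihood`, optionally `fish_id`/`trial`).
#' @param keypoint Keypoint to gate (default `"head"`).
#' @param threshold Confidence cutoff in (0, 1]; the conventional value for
#'   these recordings is 0.999.
#' @return The table with gated coordinates and a `filter_report` attribute
#'   (see [filter_report()]).
#' @export
likelihood_gate <- function(tracks, keypoint = "head", threshold = 0.999) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!keypoint %in% tracks$keypoint) {
    abort(paste0("Unknown keypoint '", keypoint, "'."))
  }
  hit <- tracks$keypoint == keypoint & !is.na(tracks$likelihood) &
    tracks$likelihood < threshold
  newly <- hit & !is.na(tracks$x)
  out <- tracks
  out$x[hit] <- NA_real_
  out$y[hit] <- NA_real_
  gb <- track_groups(tracks)
  rep_tbl <- out[newly, , drop = FALSE] |>
    count_by_group(gb, stage = "likelihood_gate", keypoint = keypoint,
                   template = out)
  out <- restore_track_attrs(out, tracks)
  add_report(out, rep_tbl)
}

# count masked/filled rows per track group, keeping zero-count groups
count_by_group <- function(rows, gb, stage, keypoint, template) {
  all_groups <- distinct(as_tibble(template)[, gb, drop = FALSE])
  if (length(gb) == 0L) {
    return(tibble(stage = stage, keypoint = keypoint, n = nrow(rows)))
  }
  counts <- rows |>
    as_tibble() |>
    count(across(all_of(gb)), name = "n")
  all_groups |>
    left_join(counts, by = gb) |>
    mutate(n = dplyr::coalesce(.data$n, 0L), stage = stage,
           keypoint = keypoint, .before = 1L)
}

#' Remove jump anomalies using a pooled step-distance quantile
#'
#' Euclidean distances between consecutive non-missing observations of a
#' track (frames already masked, e.g. by the likelihood gate, are skipped
#' over) are pooled across every track in `tracks`. Distances strictly
#' greater than the (1 - quantile) sample quantile of that pooled
#' distribution mark the second frame of the pair as an anomaly, in a
#' single pass over the distances computed up front. Ties at the threshold
#' are not flagged. Comparing across gaps is what keeps a jump artifact
#' detectable when the frame before it happened to be gated.
#'
#' @inheritParams likelihood_gate
#' @param quantile Upper tail fraction to flag (default 0.05, i.e. the top
#'   5\% of pooled step distances).
#' @return Masked table with a `filter_report` attribute.
#' @export
jump_filter <- function(tracks, keypoint = "head", quantile = 0.05) {
  stopifnot(quantile > 0, quantile < 1)
  if (!keypoint %in% tracks$keypoint) {
    abort(paste0("Unknown keypoint '", keypoint, "'."))
  }
  gb <- track_groups(tracks)
  kp_idx <- which(tracks$keypoint == keypoint)
  kp <- as_tibble(tracks)[kp_idx, ]
  key <- if (length(gb)) do.call(paste, c(kp[gb], sep = "\r")) else
    rep("", nrow(kp))
  ord <- order(key, kp$frame)
  kp <- kp[ord, ]
  key <- key[ord]
  obs <- which(!is.na(kp$x))
  if (length(obs)) {
    prev <- c(NA_integer_, obs[-length(obs)])
    same <- !is.na(prev) & key[obs] == key[prev]
    d <- rep(NA_real_, length(obs))
    d[same] <- sqrt((kp$x[obs] - kp$x[prev])^2 +
                      (kp$y[obs] - kp$y[prev])^2)[same]
  } else {
    d <- numeric(0)
  }
  pool <- d[!is.na(d)]
  if (length(pool) == 0L) abort("no distances: fewer than 2 non-missing frames in every track")
  thr <- pctl(pool, 1 - quantile)
  flag <- !is.na(d) & d > thr
  out <- tracks
  masked_rows <- kp_idx[ord][obs[flag]]
  out$x[masked_rows] <- NA_real_
  out$y[masked_rows] <- NA_real_
  rep_tbl <- out[masked_rows, , drop = FALSE] |>
    count_by_group(gb, stage = "jump_filter", keypoint = keypoint,
                   template = out)
  out <- restore_track_attrs(out, tracks)
  out <- add_report(out, rep_tbl)
  attr(out, "jump_threshold") <- thr
  out
}

#' Fill interior missing coordinates by natural cubic-spline interpolation
#'
#' Missing `x`/`y` values lying between observed frames are replaced by the
#' value of the natural cubic spline (second derivative zero at the end
#' knots) through the observed (frame, coordinate) points. Leading and
#' trailing missing runs are never extrapolated. Tracks with fewer than four
#' observed frames pass through unchanged with a warning.
#'
#' @inheritParams likelihood_gate
#' @return Filled table with a `filter_report` attribute; the report carries
#'   stages `spline_fill` (frames filled) and `residual_missing` (frames
#'   still missing afterwards).
#' @export
spline_interpolate <- function(tracks, keypoint = "head") {
  if (!keypoint %in% tracks$keypoint) {
    abort(paste0("Unknown keypoint '", keypoint, "'."))
  }
  gb <- track_groups(tracks)
  out <- as_tibble(tracks)
  idx_all <- which(out$keypoint == keypoint)
  kp <- out[idx_all, ]
  key <- if (length(gb)) do.call(paste, c(kp[gb], sep = "\r")) else
    rep("", nrow(kp))
  filled_rows <- integer(0)
  warned <- FALSE
  for (k in unique(key)) {
    rows <- idx_all[key == k]
    rows <- rows[order(out$frame[rows])]
    obs <- !is.na(out$x[rows])
    if (sum(obs) < 4L) {
      if (any(!obs)) warned <- TRUE
      next
    }
    if (all(obs)) next
    f <- out$frame[rows]
    lo <- min(f[obs]); hi <- max(f[obs])
    interior <- !obs & f > lo & f < hi
    if (!any(interior)) next
    for (col in c("x", "y")) {
      sf <- stats::splinefun(f[obs], out[[col]][rows][obs],
                             method = "natural")
      out[[col]][rows[interior]] <- sf(f[interior])
    }
    filled_rows <- c(filled_rows, rows[interior])
  }
  if (warned) {
    warn("Track(s) with fewer than 4 observed frames passed through unfilled.")
  }
  fill_rep <- out[filled_rows, , drop = FALSE] |>
    count_by_group(gb, stage = "spline_fill", keypoint = keypoint,
                   template = out)
  resid <- out[idx_all[is.na(out$x[idx_all])], , drop = FALSE] |>
    count_by_group(gb, stage = "residual_missing", keypoint = keypoint,
                   template = out)
  out <- restore_track_attrs(out, tracks)
  add_report(out, bind_rows(fill_rep, resid))
}

#' Run the full three-step prefilter on a track table
#'
#' Applies, in fixed order, likelihood gating, the pooled jump filter, and
#' natural cubic-spline interpolation, for each keypoint listed.
#'
#' @inheritParams likelihood_gate
#' @param keypoints Character vector of keypoints to preprocess.
#' @param likelihood_threshold Confidence cutoff for [likelihood_gate()].
#' @param jump_quantile Upper tail fraction for [jump_filter()].
#' @return The preprocessed table. [filter_report()] returns per-track,
#'   per-keypoint counts for all stages; [preprocess_report()] pivots them
#'   into one row per track with `n_gated`, `n_anomalies`, `n_interpolated`,
#'   `n_residual_missing`.
#' @export
preprocess_tracks <- function(tracks, keypoints = "head",
                              likelihood_threshold = 0.999,
                              jump_quantile = 0.05) {
  out <- tracks
  for (kp in keypoints) {
    out <- likelihood_gate(out, kp, likelihood_threshold)
    out <- jump_filter(out, kp, jump_quantile)
    out <- spline_interpolate(out, kp)
  }
  out
}

#' @rdname preprocess_tracks
#' @param x A table returned by [preprocess_tracks()].
#' @export
preprocess_report <- function(x) {
  rep_tbl <- filter_report(x)
  if (is.null(rep_tbl)) abort("No filter report attached; run preprocess_tracks() first.")
  rep_tbl |>
    mutate(stage = dplyr::recode(.data$stage,
                                 likelihood_gate = "n_gated",
                                 jump_filter = "n_anomalies",
                                 spline_fill = "n_interpolated",
                                 residual_missing = "n_residual_missing")) |>
    pivot_wider(names_from = "stage", values_from = "n", values_fill = 0L)
}

#' Preprocess every track of a session
#'
#' @param session A `killicog_session` (see [load_session()],
#'   [simulate_tracks()]).
#' @inheritParams preprocess_tracks
#' @return The session with `$tracks` replaced by the preprocessed table and
#'   a `$report` element (one row per track and keypoint).
#' @export
preprocess_session <- function(session, keypoints = "head",
                               likelihood_threshold = 0.999,
                               jump_quantile = 0.05) {
  stopifnot(inherits(session, "killicog_session"))
  session$tracks <- preprocess_tracks(session$tracks, keypoints,
                                      likelihood_threshold, jump_quantile)
  session$report <- preprocess_report(session$tracks)
  session
}
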