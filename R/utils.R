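# Shared internal helpers.

# Round half away from zero (report convention for percent fields); base
# round() is round-half-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Sample quantile with linear interpolation between order statistics
# (type 7), the single percentile definition used package-wide.
pctl <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE)
}

# Grouping columns present on a long track/kinematics table. A bare
# single-track table may carry neither fish_id nor trial.
track_groups <- function(df) intersect(c("fish_id", "trial"), names(df))

# fps attached to a track table (attribute set by readers/generators),
# overridable by an explicit argument.
track_fps <- function(df, fps = NULL) {
  fps <- fps %||% attr(df, "fps") %||% 20
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  fps
}

# Maximal runs of TRUE in a logical vector (NA counts as FALSE); returns a
# tibble of start/end indices, zero rows if none.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Append a stage row to the filter-report attribute carried by track tables.
add_report <- function(df, report_rows) {
  old <- attr(df, "filter_report")
  attr(df, "filter_report") <- bind_rows(old, report_rows)
  df
}

#' Retrieve the per-stage filter report attached to a track table
#'
#' Preprocessing stages ([likelihood_gate()], [jump_filter()],
#' [spline_interpolate()]) annotate the returned table with counts of frames
#' masked or filled, per track and keypoint.
#'
#' @param x A track table returned by a preprocessing stage.
#' @return A tibble with columns `stage`, the grouping columns present,
#'   `keypoint`, and `n` (frames affected), or `NULL` if no stage has run.
#' @export
filter_report <- function(x) attr(x, "filter_report")

# Restore track attributes (fps, class) after dplyr operations drop them.
restore_track_attrs <- function(new, old) {
  attr(new, "fps") <- attr(old, "fps")
  attr(new, "filter_report") <- attr(new, "filter_report") %||% attr(old, "filter_report")
  class(new) <- unique(c(setdiff(class(old), class(new)), class(new)))
  new
}
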