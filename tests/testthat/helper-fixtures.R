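# Small in-code fixtures.

# A bare single-track tibble (no fish/trial columns).
make_track <- function(n = 40, keypoints = "head", fps = 20,
                       x = NULL, y = NULL, likelihood = 1) {
  out <- purrr::map(keypoints, function(kp) {
    tibble::tibble(
      frame = seq_len(n) - 1L,
      keypoint = kp,
      x = x %||% seq_len(n) + 0,
      y = y %||% rep(100, n),
      likelihood = rep(likelihood, length.out = n)
    )
  }) |> purrr::list_rbind()
  attr(out, "fps") <- fps
  out
}

# A minimal kinematics-like tibble for learning-module unit tests.
make_kin <- function(trial = 1L, fish_id = "f01", v = NULL, dist = NULL,
                     n = length(v %||% dist), fps = 20) {
  tibble::tibble(
    fish_id = fish_id, trial = trial,
    frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) / fps,
    v_up = v %||% rep(0, n), v_up_rolled = v %||% rep(0, n),
    dist_food = dist %||% rep(1000, n)
  )
}

`%||%` <- rlang::`%||%`

# Write a raw DLC-dialect CSV from header rows + body lines.
write_dlc_lines <- function(path, parts, coords, body) {
  lines <- c(
    paste(c("scorer", rep("s", length(parts))), collapse = ","),
    paste(c("bodyparts", parts), collapse = ","),
    paste(c("coords", coords), collapse = ","),
    body
  )
  writeLines(lines, path)
  path
}
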