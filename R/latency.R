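#' Extract the four typing latency series from keystroke events
#'
#' For a session with press times \eqn{P_1 \dots P_n} and release times
#' \eqn{R_1 \dots R_n} (press-time order over all keys, specials included):
#' hold latency \eqn{HL_i = R_i - P_i}, interkey latency
#' \eqn{IL_i = P_{i+1} - R_i}, press latency \eqn{PL_i = P_{i+1} - P_i},
#' release latency \eqn{RL_i = R_{i+1} - R_i}. IL may be negative under
#' rollover typing (the next key is pressed before the previous is released);
#' negative values are retained here — removal is the outlier policy's job.
#'
#' @param events Event tibble (one or more sessions); every session needs at
#'   least 2 events.
#' @return Tibble with columns `subject_id`, `visit_index`, `kind`
#'   (`"HL"/"IL"/"PL"/"RL"`), `index` (position of the first source event),
#'   `value` (seconds), and the source keys `key_from`, `key_to` for
#'   traceability.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   subject_id = "S1", visit_index = 1L, key_id = c("a", "b", "c"),
#'   press_time = c(0, 0.5, 0.6), release_time = c(0.1, 0.65, 0.8)
#' )
#' extract_latencies(ev)
extract_latencies <- function(events) {
  stopifnot_cols(events, c("subject_id", "visit_index", "key_id",
                           "press_time", "release_time"), "events")
  idx <- split(seq_len(nrow(events)),
               paste(events$subject_id, events$visit_index, sep = "\r"),
               drop = TRUE)
  parts <- lapply(idx, function(i) {
    i <- i[order(events$press_time[i], events$release_time[i],
                 events$key_id[i])]
    p <- events$press_time[i]
    r <- events$release_time[i]
    k <- events$key_id[i]
    n <- length(i)
    if (n < 2) {
      abort(sprintf("insufficient events (%d) for subject %s visit %s",
                    n, events$subject_id[i[1]], events$visit_index[i[1]]))
    }
    tibble(
      subject_id = events$subject_id[i[1]],
      visit_index = events$visit_index[i[1]],
      kind = rep(c("HL", "IL", "PL", "RL"), c(n, n - 1L, n - 1L, n - 1L)),
      index = c(seq_len(n), rep(seq_len(n - 1L), 3)),
      value = c(r - p, p[-1] - r[-n], diff(p), diff(r)),
      key_from = c(k, rep(k[-n], 3)),
      key_to = c(k, rep(k[-1], 3))
    )
  })
  dplyr::bind_rows(parts)
}

#' Typing speed and word count per session
#'
#' A "word" is counted as one space press, plus one trailing word if any
#' non-space key occurs (a documented convention — raw logs carry no text).
#' Speed is words per minute over the elapsed session time (last release
#' minus first press).
#'
#' @param events Event tibble.
#' @return Tibble with one row per session: `subject_id`, `visit_index`,
#'   `n_keystrokes`, `word_count`, `elapsed_min`, `typing_speed` (words/min).
#' @export
typing_summary <- function(events) {
  stopifnot_cols(events, c("subject_id", "visit_index", "key_id",
                           "press_time", "release_time"), "events")
  out <- dplyr::summarise(
    dplyr::group_by(events, .data$subject_id, .data$visit_index),
    n_keystrokes = dplyr::n(),
    word_count = sum(.data$key_id == "space") +
      as.integer(any(.data$key_id != "space")),
    elapsed_min = (max(.data$release_time) - min(.data$press_time)) / 60,
    .groups = "drop"
  )
  if (any(out$elapsed_min <= 0)) {
    abort(sprintf("zero elapsed time for subject(s): %s",
                  paste(out$subject_id[out$elapsed_min <= 0], collapse = ", ")))
  }
  dplyr::mutate(out, typing_speed = .data$word_count / .data$elapsed_min)
}
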