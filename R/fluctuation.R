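#' Log-ratio fluctuation statistic
#'
#' The sample standard deviation (n−1 denominator) of the natural log of the
#' quotient of two consecutive time intervals,
#' \eqn{sd\{\ln(v_{i+1}/v_i)\}}. It is scale-free (multiplying the series by
#' any positive constant leaves it unchanged) and sequential: permuting the
#' series generally changes it, because it measures step-to-step fluctuation,
#' not marginal spread.
#'
#' Non-positive values cannot enter a log-ratio; they are excluded with both
#' adjacent ratios dropped. With `pairing = "compact"` (default) ratios are
#' formed between consecutive survivors of cleaning — the series is
#' compacted; `"strict"` only pairs values that were adjacent in the original
#' series (requires `index`).
#'
#' @param values Numeric interval series (cleaned, ideally all positive).
#' @param index Original positions of `values` in the uncleaned series;
#'   needed for `pairing = "strict"`.
#' @param pairing `"compact"` or `"strict"`.
#' @return The statistic, or `NA` when fewer than 2 valid ratios remain
#'   (never a fabricated zero).
#' @export
#' @examples
#' log_ratio_sd(c(0.2, 0.2, 0.2, 0.2))   # 0: all ratios are 1
#' log_ratio_sd(c(1, 2, 4, 8))           # 0: constant ratio
#' log_ratio_sd(c(0.1, 0.2, 0.1, 0.2))   # sd of {ln 2, -ln 2, ln 2}
log_ratio_sd <- function(values, index = NULL, pairing = c("compact", "strict")) {
  pairing <- match.arg(pairing)
  values <- as.numeric(values)
  ok <- !is.na(values)
  values <- values[ok]
  if (is.null(index)) {
    index <- seq_along(values)
  } else {
    index <- index[ok]
  }
  n <- length(values)
  if (n < 3) return(NA_real_)
  valid <- values[-n] > 0 & values[-1] > 0
  if (pairing == "strict") valid <- valid & (diff(index) == 1L)
  logr <- log(values[-1][valid] / values[-n][valid])
  if (length(logr) < 2) return(NA_real_)
  # a constant-ratio series has zero fluctuation by definition; short-circuit
  # so summation rounding cannot produce a spurious 1e-17
  if (max(logr) == min(logr)) return(0)
  sd(logr)
}

# keys admitted by the restricted (published-method) filter:
# letters, digits, printable punctuation/symbols, and the space bar
is_restricted_key <- function(key) {
  key == "space" | grepl("^[a-z0-9[:punct:]]$", key)
}

#' Restrict latency values to alphanumeric/symbol/space keystrokes
#'
#' The published fluctuation method only admitted alphanumeric, symbol and
#' space-bar keys; this filter reproduces that restriction. A value survives
#' only if all of its source events are admissible (special keys such as
#' backspace, enter, shift, arrows are excluded).
#'
#' @param latencies Latency tibble from [extract_latencies()].
#' @return The filtered latency tibble (possibly empty).
#' @export
restricted_keys <- function(latencies) {
  stopifnot_cols(latencies, c("key_from", "key_to"), "latencies")
  dplyr::filter(latencies, is_restricted_key(.data$key_from) &
                  is_restricted_key(.data$key_to))
}

# fast per-session feature core working on plain vectors
session_features <- function(p, r, k, policy, pairing) {
  n <- length(p)
  series <- list(HL = r - p, IL = p[-1] - r[-n], PL = diff(p), RL = diff(r))
  stats <- rep(NA_real_, 4L)
  names(stats) <- names(series)
  rep_rows <- vector("list", 4L)
  for (j in seq_along(series)) {
    v <- series[[j]]
    cl <- clean_values(v, policy)
    stats[j] <- log_ratio_sd(v[cl$keep], index = cl$keep, pairing = pairing)
    n_removed <- cl$n_negative_removed + cl$n_iqr_removed
    rep_rows[[j]] <- list(kind = names(series)[j], n_input = cl$n_input,
                          n_negative_removed = cl$n_negative_removed,
                          n_iqr_removed = cl$n_iqr_removed,
                          pct_removed = 100 * n_removed / cl$n_input,
                          too_short = length(cl$keep) < 3)
  }
  # restricted-key hold-latency variant ("SD" of the published method)
  hl <- series$HL
  adm <- is_restricted_key(k)
  v <- hl[adm]
  sd_restricted <- if (length(v) >= 3) {
    cl <- clean_values(v, policy)
    log_ratio_sd(v[cl$keep], index = cl$keep, pairing = pairing)
  } else {
    NA_real_
  }
  spaces <- sum(k == "space")
  word_count <- spaces + as.integer(any(k != "space"))
  elapsed_min <- (max(r) - p[1]) / 60
  if (elapsed_min <= 0) abort("zero elapsed time in session")
  list(stats = stats, sd_restricted = sd_restricted,
       word_count = word_count, elapsed_min = elapsed_min,
       n_keystrokes = n, report = rep_rows)
}

#' Build per-subject keystroke feature records
#'
#' Runs the full per-session chain — latency extraction, outlier cleaning per
#' latency kind, log-ratio fluctuation statistic per kind (all keystrokes),
#' the restricted-key hold-latency variant (`sd_restricted`), typing speed
#' and word count — and joins subject metadata. Statistics are `NA` (never
#' zero) when a cleaned series has fewer than 3 values.
#'
#' @param events Event tibble, one session per subject (see
#'   [select_first_visit()]).
#' @param metadata Optional metadata tibble (see [read_subject_metadata()]).
#' @param policy An [outlier_policy()].
#' @param pairing Ratio pairing across removed values; see [log_ratio_sd()].
#' @return Feature tibble, one row per subject, with an `outlier_report`
#'   attribute (as in [clean_latencies()]).
#' @export
compute_features <- function(events, metadata = NULL,
                             policy = outlier_policy(),
                             pairing = c("compact", "strict")) {
  pairing <- match.arg(pairing)
  stopifnot_cols(events, c("subject_id", "visit_index", "key_id",
                           "press_time", "release_time"), "events")
  idx <- split(seq_len(nrow(events)),
               paste(events$subject_id, events$visit_index, sep = "\r"),
               drop = TRUE)
  feat <- vector("list", length(idx))
  reports <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    if (length(i) < 2) {
      abort(sprintf("insufficient events for subject %s",
                    events$subject_id[i[1]]))
    }
    i <- i[order(events$press_time[i], events$release_time[i],
                 events$key_id[i])]
    sf <- session_features(events$press_time[i], events$release_time[i],
                           events$key_id[i], policy, pairing)
    feat[[j]] <- tibble(
      subject_id = events$subject_id[i[1]],
      visit_index = events$visit_index[i[1]],
      hl_sd = sf$stats[["HL"]], il_sd = sf$stats[["IL"]],
      pl_sd = sf$stats[["PL"]], rl_sd = sf$stats[["RL"]],
      sd_restricted = sf$sd_restricted,
      typing_speed = sf$word_count / sf$elapsed_min,
      word_count = sf$word_count,
      n_keystrokes = sf$n_keystrokes
    )
    reports[[j]] <- tibble(
      subject_id = events$subject_id[i[1]],
      visit_index = events$visit_index[i[1]],
      kind = vapply(sf$report, `[[`, "", "kind"),
      n_input = vapply(sf$report, `[[`, 0L, "n_input"),
      n_negative_removed = vapply(sf$report, `[[`, 0L, "n_negative_removed"),
      n_iqr_removed = vapply(sf$report, `[[`, 0L, "n_iqr_removed"),
      pct_removed = vapply(sf$report, `[[`, 0, "pct_removed"),
      too_short = vapply(sf$report, `[[`, NA, "too_short")
    )
  }
  features <- dplyr::bind_rows(feat)
  report <- dplyr::bind_rows(reports)
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    features <- dplyr::left_join(
      features,
      metadata[, intersect(c("subject_id", "group", "updrs3", "stap",
                             "aftap", "nqi"), names(metadata))],
      by = "subject_id"
    )
  }
  cols <- intersect(feature_columns, names(features))
  features <- features[, c(cols, setdiff(names(features), cols))]
  structure(dplyr::arrange(features, .data$subject_id),
            outlier_report = dplyr::arrange(report, .data$subject_id,
                                            .data$kind))
}
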