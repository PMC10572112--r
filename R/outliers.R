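#' Outlier-removal policy for latency series
#'
#' Cleaning follows a two-step rule: intervals that are negative are invalid
#' a priori and dropped first; then an interquartile-range fence
#' \eqn{[Q1 - k \cdot IQR,\; Q3 + k \cdot IQR]} is computed on the remaining
#' values (so invalid negatives cannot shift the quartiles) and values
#' outside it are dropped. The textbook extreme-outlier fence uses
#' \eqn{k = 3}; raw typing logs carry rare but enormous glitch values, and a
#' wide \eqn{k = 12} operating fence removes those while retaining the heavy
#' but meaningful right tail of latency distributions, so 12 is the default.
#'
#' @param k Positive fence multiplier (default 12).
#' @param quantile_type Quantile convention, 1–9 as in [stats::quantile()];
#'   default 7 (linear interpolation between order statistics). Pinned
#'   because statistics packages differ.
#' @param drop_negative Drop negative values before computing the fence.
#' @return An `outlier_policy` object.
#' @export
outlier_policy <- function(k = 12, quantile_type = 7L, drop_negative = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    abort("`k` must be a positive number")
  }
  if (!quantile_type %in% 1:9) abort("`quantile_type` must be in 1..9")
  structure(list(k = k, quantile_type = as.integer(quantile_type),
                 drop_negative = isTRUE(drop_negative)),
            class = "outlier_policy")
}

#' IQR fence bounds
#'
#' @param values Numeric vector, non-empty.
#' @param k Fence multiplier.
#' @param quantile_type Quantile convention (see [outlier_policy()]).
#' @return `c(lower, upper)` with `lower = Q1 - k*IQR`, `upper = Q3 + k*IQR`.
#' @export
#' @examples
#' iqr_bounds(1:8, k = 3)   # Q1 = 2.75, Q3 = 6.25 -> c(-7.75, 16.75)
iqr_bounds <- function(values, k = 3, quantile_type = 7L) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("empty input to iqr_bounds()")
  q <- quantile(values, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

# vector core: returns survivor positions + removal counts
clean_values <- function(values, policy) {
  keep <- seq_along(values)
  n_neg <- 0L
  if (policy$drop_negative) {
    neg <- values < 0
    n_neg <- sum(neg)
    keep <- keep[!neg]
  }
  n_iqr <- 0L
  if (length(keep) > 0) {
    b <- iqr_bounds(values[keep], policy$k, policy$quantile_type)
    out <- values[keep] < b[1] | values[keep] > b[2]
    n_iqr <- sum(out)
    keep <- keep[!out]
  }
  list(keep = keep, n_input = length(values),
       n_negative_removed = n_neg, n_iqr_removed = n_iqr)
}

#' Clean latency series with an outlier policy
#'
#' Applies [outlier_policy()] independently per subject, session and latency
#' kind; survivor order is preserved. The per-series removal report (the
#' basis of an outliers-removed table) is attached as attribute
#' `"outlier_report"` — read it with [outlier_report()] straight after
#' cleaning, before further dplyr verbs drop attributes.
#'
#' @param latencies Latency tibble from [extract_latencies()].
#' @param policy An [outlier_policy()].
#' @return The cleaned latency tibble, with an `outlier_report` attribute:
#'   one row per (subject, visit, kind) with `n_input`,
#'   `n_negative_removed`, `n_iqr_removed`, `pct_removed` (percent of input)
#'   and `too_short` (fewer than 3 survivors — downstream statistics refuse
#'   such series).
#' @export
clean_latencies <- function(latencies, policy = outlier_policy()) {
  stopifnot_cols(latencies, c("subject_id", "visit_index", "kind", "value"),
                 "latencies")
  idx <- split(seq_len(nrow(latencies)),
               paste(latencies$subject_id, latencies$visit_index,
                     latencies$kind, sep = "\r"), drop = TRUE)
  keep_all <- vector("list", length(idx))
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    cl <- clean_values(latencies$value[i], policy)
    keep_all[[j]] <- i[cl$keep]
    n_removed <- cl$n_negative_removed + cl$n_iqr_removed
    rows[[j]] <- tibble(
      subject_id = latencies$subject_id[i[1]],
      visit_index = latencies$visit_index[i[1]],
      kind = latencies$kind[i[1]],
      n_input = cl$n_input,
      n_negative_removed = cl$n_negative_removed,
      n_iqr_removed = cl$n_iqr_removed,
      pct_removed = 100 * n_removed / cl$n_input,
      too_short = length(cl$keep) < 3
    )
  }
  report <- dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id,
                           .data$visit_index, .data$kind)
  if (any(report$too_short)) {
    warn(sprintf("%d series have < 3 survivors after cleaning",
                 sum(report$too_short)))
  }
  out <- latencies[sort(unlist(keep_all)), ]
  structure(out, outlier_report = report)
}

#' @rdname clean_latencies
#' @param cleaned The tibble returned by `clean_latencies()`.
#' @export
outlier_report <- function(cleaned) {
  rep <- attr(cleaned, "outlier_report")
  if (is.null(rep)) abort("no outlier report attached; pass the direct result of clean_latencies()")
  as_tibble(rep)
}

#' Pool an outlier report per subject
#'
#' Aggregates the per-kind report over the four latency kinds, giving the
#' per-subject percentage of removed time points (the usual way such removal
#' rates are tabulated).
#'
#' @param report Per-kind report from [outlier_report()].
#' @return One row per subject/visit with pooled counts and `pct_removed`.
#' @export
pool_outlier_report <- function(report) {
  dplyr::mutate(
    dplyr::summarise(
      dplyr::group_by(report, .data$subject_id, .data$visit_index),
      n_input = sum(.data$n_input),
      n_negative_removed = sum(.data$n_negative_removed),
      n_iqr_removed = sum(.data$n_iqr_removed),
      .groups = "drop"
    ),
    pct_removed = 100 * (.data$n_negative_removed + .data$n_iqr_removed) /
      .data$n_input
  )
}
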