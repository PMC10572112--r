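# ---- vector cores ------------------------------------------------------

# Mann-Whitney AUC (ties counted 1/2): P(case > control) + P(=)/2
auc_mw <- function(cases, controls) {
  n1 <- length(cases)
  n0 <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# thresholds: midpoints between adjacent distinct scores, plus +/-Inf sentinels
roc_thresholds <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) > 1) {
    c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
}

# staircase under cases_higher orientation: positive when score > threshold
roc_points_core <- function(cases, controls) {
  thr <- roc_thresholds(c(cases, controls))
  tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(cases > t), 0),
    specificity = vapply(thr, function(t) mean(controls <= t), 0)
  )
}

trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$specificity
  o <- order(fpr, roc$sensitivity)
  fpr <- fpr[o]
  tpr <- roc$sensitivity[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Clopper-Pearson on round(AUC * n) successes in n = n_cases + n_controls
# trials: the exact-binomial convention of clinical ROC tabulation software.
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# DeLong placement values for one feature
placements <- function(cases, controls) {
  cmp <- outer(cases, controls, FUN = function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

youden_pick <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[roc$sensitivity[best] >= max(roc$sensitivity[best]) - 1e-12]
  # "lower threshold in the case direction": on the internal cases_higher
  # scale that is the smallest threshold; a flipped (cases_lower) feature
  # maps back to the largest original-scale cutoff.
  i <- best[which.min(roc$threshold[best])]
  roc[i, , drop = FALSE]
}

default_orientations <- c(
  aftap = "cases_lower", stap = "cases_lower", typing_speed = "cases_lower",
  word_count = "cases_lower", n_keystrokes = "cases_lower",
  hl_sd = "cases_higher", il_sd = "cases_higher", pl_sd = "cases_higher",
  rl_sd = "cases_higher", sd_restricted = "cases_higher",
  nqi = "cases_higher", updrs3 = "cases_higher"
)

resolve_orientation <- function(feature, orientation, cases, controls) {
  if (!is.null(orientation)) return(match.arg(orientation,
                                              c("cases_higher", "cases_lower")))
  if (feature %in% names(default_orientations)) {
    return(default_orientations[[feature]])
  }
  # auto-orient fallback: flip if the raw AUC is below 0.5
  flip <- auc_mw(cases, controls) < 0.5
  inform(sprintf("auto-orienting '%s' as %s", feature,
                 if (flip) "cases_lower" else "cases_higher"))
  if (flip) "cases_lower" else "cases_higher"
}

# ---- user-facing screening ---------------------------------------------

#' Screen one feature's ability to separate cases from controls
#'
#' Builds the empirical ROC staircase (thresholds at midpoints between
#' adjacent distinct scores plus infinite sentinels), the AUC (trapezoid,
#' identical to the Mann–Whitney probability with ties counted 1/2), an
#' exact binomial (Clopper–Pearson) 95% CI treating `round(AUC * n)` of
#' `n = n_cases + n_controls` as binomial successes, and the
#' maximal-Youden-index operating point (`J = sensitivity + specificity - 1`;
#' ties broken towards higher sensitivity, then the lower threshold in the
#' case direction). Subjects with a missing score are dropped for this
#' feature only, with counts recorded.
#'
#' @param data Feature tibble (one row per subject).
#' @param feature Column name of the score to screen.
#' @param case_group,control_group Values of `group_col` defining the
#'   contrast.
#' @param group_col Grouping column (default `"group"`).
#' @param orientation `"cases_higher"`, `"cases_lower"`, or `NULL` to use the
#'   built-in direction map (tapping scores and typing speed run lower in
#'   patients; fluctuation statistics and nQi run higher), falling back to
#'   auto-orientation with a message for unknown features.
#' @return A `screening_result`: feature name, orientation, ROC tibble,
#'   `auc`, `auc_ci95`, Youden `cutoff` with sensitivity/specificity (both as
#'   fractions and percents), sample sizes and number dropped as missing.
#' @export
screen_feature <- function(data, feature, case_group, control_group,
                           group_col = "group", orientation = NULL) {
  stopifnot_cols(data, c(feature, group_col), "feature table")
  g <- data[[group_col]]
  if (!case_group %in% g || !control_group %in% g) {
    abort(sprintf("need both classes present: %s, %s", case_group, control_group))
  }
  x <- data[[feature]]
  cases <- x[g %in% case_group]
  controls <- x[g %in% control_group]
  n_missing <- sum(is.na(cases)) + sum(is.na(controls))
  cases <- cases[!is.na(cases)]
  controls <- controls[!is.na(controls)]
  if (length(cases) == 0 || length(controls) == 0) {
    abort(sprintf("'%s': a class has no non-missing scores", feature))
  }
  orientation <- resolve_orientation(feature, orientation, cases, controls)
  s <- if (orientation == "cases_lower") -1 else 1
  roc <- roc_points_core(s * cases, s * controls)
  auc <- auc_mw(s * cases, s * controls)
  n <- length(cases) + length(controls)
  ci <- clopper_pearson(round(auc * n), n)
  best <- youden_pick(roc)
  roc_out <- roc
  roc_out$threshold <- s * roc_out$threshold
  structure(list(
    feature = feature, orientation = orientation,
    case_group = case_group, control_group = control_group,
    roc = roc_out, auc = auc, auc_ci95 = ci,
    cutoff = s * best$threshold,
    sensitivity = best$sensitivity, specificity = best$specificity,
    youden = best$sensitivity + best$specificity - 1,
    n_cases = length(cases), n_controls = length(controls),
    n_missing_dropped = n_missing
  ), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening: %s (%s vs %s, %s)\n", x$feature, x$case_group,
              x$control_group, x$orientation))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), n = %d cases / %d controls\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$n_cases, x$n_controls))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.0f%%, specificity %.0f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @export
glance.screening_result <- function(x, ...) {
  tibble(feature = x$feature, orientation = x$orientation,
         case_group = x$case_group, control_group = x$control_group,
         n_cases = x$n_cases, n_controls = x$n_controls,
         auc = x$auc, ci_low = x$auc_ci95[[1]], ci_high = x$auc_ci95[[2]],
         cutoff = x$cutoff,
         sensitivity = round(100 * x$sensitivity),
         specificity = round(100 * x$specificity),
         sensitivity_frac = x$sensitivity, specificity_frac = x$specificity)
}

#' @export
tidy.screening_result <- function(x, ...) {
  dplyr::mutate(x$roc, feature = x$feature, .before = 1)
}

#' @export
autoplot.screening_result <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s: %s vs %s", object$feature, object$case_group,
                      object$control_group),
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc,
                         object$auc_ci95[1], object$auc_ci95[2])
    ) +
    ggplot2::theme_minimal()
}

#' Screen several features at once
#'
#' @inheritParams screen_feature
#' @param features Character vector of score columns.
#' @param orientations Optional named character vector overriding the
#'   per-feature direction map.
#' @return Tibble with one row per feature (the [generics::glance()] of each
#'   [screen_feature()] fit) and a `result` list-column of the full fits.
#' @export
screen_features <- function(data, features, case_group, control_group,
                            group_col = "group", orientations = NULL) {
  fits <- lapply(features, function(f) {
    tryCatch(
      screen_feature(data, f, case_group, control_group, group_col,
                     orientation = orientations[[f]] %||% NULL),
      error = function(e) {
        inform(sprintf("screening skipped for '%s' (%s vs %s): %s", f,
                       case_group, control_group, conditionMessage(e)))
        NULL
      })
  })
  fits <- fits[!vapply(fits, is.null, NA)]
  if (length(fits) == 0) abort("no screenable features")
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$result <- fits
  out
}

#' DeLong test for two paired (correlated) AUCs
#'
#' Compares the AUCs of two features measured on the same subjects using the
#' nonparametric placement-value covariance construction: per-case and
#' per-control placement values for each feature, their empirical covariance
#' matrices, `z = (AUC_a - AUC_b) / sqrt(var(diff))`, two-sided normal
#' p-value. Only subjects with both features present enter (`n_paired`
#' recorded).
#'
#' @inheritParams screen_feature
#' @param feature_a,feature_b Score columns to compare.
#' @param orientations Optional named vector as in [screen_features()].
#' @return One-row tibble: AUCs, variance of the difference, `z`, `p`,
#'   `n_paired`.
#' @export
delong_test <- function(data, feature_a, feature_b, case_group, control_group,
                        group_col = "group", orientations = NULL) {
  stopifnot_cols(data, c(feature_a, feature_b, group_col), "feature table")
  g <- data[[group_col]]
  keep <- g %in% c(case_group, control_group) &
    !is.na(data[[feature_a]]) & !is.na(data[[feature_b]])
  d <- data[keep, ]
  is_case <- d[[group_col]] %in% case_group
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    # a paired AUC comparison needs at least 2 complete subjects per class
    inform(sprintf("DeLong %s vs %s: fewer than 2 complete subjects in a class",
                   feature_a, feature_b))
    return(tibble(feature_a = feature_a, feature_b = feature_b,
                  auc_a = NA_real_, auc_b = NA_real_, var_diff = NA_real_,
                  z = NA_real_, p = NA_real_,
                  n_paired = sum(is_case) + sum(!is_case)))
  }
  ori <- function(f) resolve_orientation(f, orientations[[f]] %||% NULL,
                                         d[[f]][is_case], d[[f]][!is_case])
  sgn <- function(o) if (o == "cases_lower") -1 else 1
  sa <- sgn(ori(feature_a))
  sb <- sgn(ori(feature_b))
  pa <- placements(sa * d[[feature_a]][is_case], sa * d[[feature_a]][!is_case])
  pb <- placements(sb * d[[feature_b]][is_case], sb * d[[feature_b]][!is_case])
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(diff) > 1e-12) abort("degenerate DeLong variance with unequal AUCs")
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(feature_a = feature_a, feature_b = feature_b,
         auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
         z = z, p = p, n_paired = n1 + n0)
}

#' All pairwise DeLong comparisons among a feature set
#'
#' @inheritParams delong_test
#' @param features Character vector of score columns.
#' @return Tibble of all unordered feature pairs with DeLong z and p.
#' @export
delong_matrix <- function(data, features, case_group, control_group,
                          group_col = "group", orientations = NULL) {
  if (length(features) < 2) {
    return(tibble(feature_a = character(), feature_b = character(),
                  auc_a = numeric(), auc_b = numeric(),
                  var_diff = numeric(), z = numeric(), p = numeric(),
                  n_paired = integer()))
  }
  pairs <- utils::combn(unique(features), 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(pr) {
    delong_test(data, pr[1], pr[2], case_group, control_group, group_col,
                orientations)
  }))
}

#' Maximal-Youden operating point of an ROC staircase
#'
#' @param roc ROC tibble with `threshold`, `sensitivity`, `specificity`
#'   (e.g. from [tidy()] of a [screen_feature()] fit).
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot_cols(roc, c("threshold", "sensitivity", "specificity"), "roc")
  if (nrow(roc) == 0) abort("empty roc")
  best <- youden_pick(roc)
  tibble(cutoff = best$threshold, sensitivity = best$sensitivity,
         specificity = best$specificity,
         youden = best$sensitivity + best$specificity - 1)
}
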