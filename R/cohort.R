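# all permutations of 1..n as a matrix (n! rows); used for exact Spearman p
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sp <- all_permutations(n - 1L)
  m <- nrow(sp)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    out[((i - 1L) * m + 1L):(i * m), ] <- cbind(i, sp + (sp >= i))
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Ties receive average ranks; rho is the product-moment correlation of the
#' rank vectors. The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}; for `n <= 9` without ties the exact
#' permutation distribution is enumerated instead.
#'
#' @param x,y Numeric vectors; pairwise-complete observations are used.
#' @return One-row tibble: `rho`, `p`, `n`, `method`. `rho` is `NA` (with a
#'   reason message) when either rank vector is constant or `n < 3`.
#' @export
#' @examples
#' spearman_cor(1:3, c(10, 20, 30))
#' spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) {
    inform("spearman_cor: fewer than 3 complete pairs")
    return(tibble(rho = NA_real_, p = NA_real_, n = n, method = "none"))
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    inform("spearman_cor: constant ranks, correlation undefined")
    return(tibble(rho = NA_real_, p = NA_real_, n = n, method = "none"))
  }
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    # no ties: ranks are permutations of 1..n, so the classic d^2 formula is
    # exact and vectorises over the full permutation distribution
    perms <- all_permutations(n)
    rxm <- matrix(rx, nrow(perms), n, byrow = TRUE)
    rho_all <- 1 - 6 * rowSums((perms - rxm)^2) / (n * (n^2 - 1))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble(rho = rho, p = min(p, 1), n = n, method = method)
}

# Tukey-type (Nemenyi) pairwise comparisons on pooled mean ranks, with tie
# correction in the variance; reference distribution is the studentized range.
nemenyi_pairs <- function(values, groups) {
  groups <- as.character(groups)
  r <- rank(values)
  N <- length(r)
  lv <- unique(groups)
  k <- length(lv)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  tie_tab <- table(values)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(pr) {
    se <- sqrt(C * N * (N + 1) / 12 * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
    stat <- abs(rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    tibble(group_a = pr[1], group_b = pr[2], statistic = stat,
           p = ptukey(stat * sqrt(2), nmeans = k, df = Inf,
                      lower.tail = FALSE))
  }))
}

dunn_pairs <- function(values, groups) {
  groups <- as.character(groups)
  r <- rank(values)
  N <- length(r)
  lv <- unique(groups)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  tie_tab <- table(values)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- dplyr::bind_rows(lapply(pairs, function(pr) {
    se <- sqrt(C * N * (N + 1) / 12 * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
    z <- abs(rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    tibble(group_a = pr[1], group_b = pr[2], statistic = z,
           p = 2 * pnorm(-z))
  }))
  out$p <- p.adjust(out$p, method = "holm")
  out
}

#' Nonparametric group comparison of one feature
#'
#' Kruskal–Wallis omnibus test (tie-corrected) across the groups with a
#' Tukey-type rank post hoc: Nemenyi comparisons of pooled mean ranks against
#' the studentized-range distribution (default), or Dunn z-tests with Holm
#' adjustment (`posthoc = "dunn"`). Descriptive cells are mean ± SD per group
#' even though the tests are rank-based, matching the usual clinical-table
#' presentation. Missing values are dropped per group with `n` reported; a
#' group with fewer than 2 non-missing values is excluded (its pairs are
#' reported with `NA` p).
#'
#' @param data Feature tibble.
#' @param feature Column to compare.
#' @param group_col Grouping column.
#' @param posthoc `"nemenyi"` or `"dunn"`.
#' @return A `group_comparison`: `summary` tibble (per-group n/mean/sd),
#'   omnibus `statistic`, `df`, `p`, and `pairwise` tibble with a
#'   `significant` flag at p < 0.05.
#' @export
compare_group_feature <- function(data, feature, group_col = "group",
                                  posthoc = c("nemenyi", "dunn")) {
  posthoc <- match.arg(posthoc)
  stopifnot_cols(data, c(feature, group_col), "feature table")
  d <- data[!is.na(data[[feature]]) & !is.na(data[[group_col]]), ]
  groups_all <- unique(as.character(data[[group_col]]))
  groups_all <- groups_all[!is.na(groups_all)]
  summary <- dplyr::summarise(
    dplyr::group_by(d, group = .data[[group_col]]),
    n = dplyr::n(), mean = mean(.data[[feature]]),
    sd = sd(.data[[feature]]), .groups = "drop"
  )
  usable <- summary$group[summary$n >= 2]
  if (length(usable) < 2) {
    abort(sprintf("'%s': need >= 2 non-missing values in >= 2 groups", feature))
  }
  du <- d[d[[group_col]] %in% usable, ]
  kw <- kruskal.test(du[[feature]], factor(du[[group_col]]))
  pw <- if (posthoc == "nemenyi") {
    nemenyi_pairs(du[[feature]], du[[group_col]])
  } else {
    dunn_pairs(du[[feature]], du[[group_col]])
  }
  # report every group pair, NA where a group was unusable
  all_pairs <- utils::combn(sort(groups_all), 2, simplify = FALSE)
  pw_full <- dplyr::bind_rows(lapply(all_pairs, function(pr) {
    hit <- pw[(pw$group_a == pr[1] & pw$group_b == pr[2]) |
                (pw$group_a == pr[2] & pw$group_b == pr[1]), ]
    if (nrow(hit) == 1) {
      tibble(group_a = pr[1], group_b = pr[2], statistic = hit$statistic,
             p = hit$p)
    } else {
      tibble(group_a = pr[1], group_b = pr[2], statistic = NA_real_,
             p = NA_real_)
    }
  }))
  pw_full$significant <- !is.na(pw_full$p) & pw_full$p < 0.05
  structure(list(feature = feature, summary = summary,
                 statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, posthoc = posthoc, pairwise = pw_full),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s\n", x$feature))
  cat(sprintf("  Kruskal-Wallis H = %.3f (df %d), p = %.4g\n",
              x$statistic, x$df, x$p))
  print(x$pairwise)
  invisible(x)
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(feature = x$feature, statistic = x$statistic, df = x$df, p = x$p)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, feature = x$feature, .before = 1)
}

#' Compare many features across groups
#'
#' @inheritParams compare_group_feature
#' @param features Character vector of feature columns.
#' @return Tidy tibble: one row per feature per group with descriptive
#'   mean/sd/n, the omnibus Kruskal–Wallis p, and list-columns are avoided —
#'   pairwise p-values appear as columns `p_<groupA>_vs_<groupB>`.
#' @export
compare_groups <- function(data, features, group_col = "group",
                           posthoc = c("nemenyi", "dunn")) {
  posthoc <- match.arg(posthoc)
  dplyr::bind_rows(lapply(features, function(f) {
    cmp <- compare_group_feature(data, f, group_col, posthoc)
    wide <- cmp$summary
    wide <- tidyr::pivot_wider(
      dplyr::mutate(wide, feature = f),
      names_from = "group", values_from = c("n", "mean", "sd")
    )
    wide$kw_statistic <- cmp$statistic
    wide$kw_p <- cmp$p
    for (i in seq_len(nrow(cmp$pairwise))) {
      wide[[sprintf("p_%s_vs_%s", cmp$pairwise$group_a[i],
                    cmp$pairwise$group_b[i])]] <- cmp$pairwise$p[i]
    }
    wide
  }))
}

#' Severity correlation table
#'
#' Spearman correlations of each feature against a severity score (UPDRS-III
#' by default) within one patient group.
#'
#' @param data Feature tibble.
#' @param features Feature columns to correlate.
#' @param group Group label to restrict to (e.g. `"early_pd"`).
#' @param severity Severity column (default `"updrs3"`).
#' @param group_col Grouping column.
#' @return Tibble: `feature`, `group`, `rho`, `p`, `n`.
#' @export
correlate_features <- function(data, features, group, severity = "updrs3",
                               group_col = "group") {
  stopifnot_cols(data, c(severity, group_col), "feature table")
  d <- data[data[[group_col]] %in% group, ]
  if (sum(!is.na(d[[severity]])) < 3) {
    abort(sprintf("group '%s' has fewer than 3 subjects with %s",
                  group, severity))
  }
  dplyr::bind_rows(lapply(features, function(f) {
    res <- suppressMessages(spearman_cor(d[[f]], d[[severity]]))
    tibble(feature = f, group = group, rho = res$rho, p = res$p, n = res$n)
  }))
}
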