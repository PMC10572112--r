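default_screen_features <- c("nqi", "aftap", "sd_restricted", "il_sd", "rl_sd")

default_compare_features <- c("updrs3", "typing_speed", "word_count", "nqi",
                              "stap", "aftap", "sd_restricted", "hl_sd",
                              "il_sd", "pl_sd", "rl_sd")

default_contrasts <- list(
  c(case = "de_novo_pd", control = "control"),
  c(case = "early_pd", control = "control")
)

#' Run the full keystroke biomarker study
#'
#' End-to-end orchestration: first-visit selection, per-subject feature
#' extraction (latencies, outlier cleaning, fluctuation statistics, typing
#' speed), group comparison tables, per-contrast screening (ROC/AUC with
#' exact binomial CI, Youden cutoffs) with pairwise DeLong comparisons, and
#' severity correlation tables per patient group. Contrasts are kept
#' separate — de novo PD vs controls and early PD vs controls are screened
#' independently, never pooled into one patient group.
#'
#' @param events Event tibble (or `NULL` when `cohort` is given).
#' @param metadata Metadata tibble (or `NULL` when `cohort` is given).
#' @param cohort Optional [simulate_cohort()] result used as input.
#' @param policy An [outlier_policy()].
#' @param screen_features,compare_features Feature sets for the screening and
#'   group-comparison stages (defaults follow the published analysis).
#' @param contrasts List of `c(case =, control =)` group pairs.
#' @param orientations Optional named orientation overrides (see
#'   [screen_feature()]).
#' @param posthoc Post hoc procedure for group comparisons.
#' @return A `keystroke_study`: features, pooled and per-kind outlier
#'   reports, group comparison table, per-contrast screening tibbles and
#'   DeLong matrices, correlation tables, and the resolved configuration.
#' @export
run_study <- function(events = NULL, metadata = NULL, cohort = NULL,
                      policy = outlier_policy(),
                      screen_features = default_screen_features,
                      compare_features = default_compare_features,
                      contrasts = default_contrasts,
                      orientations = NULL,
                      posthoc = c("nemenyi", "dunn")) {
  posthoc <- match.arg(posthoc)
  if (!is.null(cohort)) {
    events <- cohort$events
    metadata <- cohort$metadata
  }
  if (is.null(events) || is.null(metadata)) {
    abort("supply either `cohort` or both `events` and `metadata`")
  }
  metadata <- validate_metadata(metadata)
  groups_present <- unique(metadata$group)
  for (ct in contrasts) {
    if (!all(ct %in% groups_present)) {
      abort(sprintf("contrast references absent group(s): %s",
                    paste(setdiff(ct, groups_present), collapse = ", ")))
    }
  }

  events <- select_first_visit(events)
  features <- compute_features(events, metadata, policy)
  outliers_by_kind <- attr(features, "outlier_report")
  outliers_pooled <- pool_outlier_report(outliers_by_kind)

  cmp_feats <- intersect(compare_features, names(features))
  cmp_feats <- cmp_feats[vapply(cmp_feats, function(f) {
    sum(!is.na(features[[f]])) >= 4
  }, NA)]
  comparisons <- dplyr::bind_rows(lapply(cmp_feats, function(f) {
    tryCatch(compare_groups(features, f, posthoc = posthoc),
             error = function(e) {
               inform(sprintf("group comparison skipped for '%s': %s",
                              f, conditionMessage(e)))
               NULL
             })
  }))

  scr_feats <- intersect(screen_features, names(features))
  screening <- list()
  delong <- list()
  for (ct in contrasts) {
    nm <- sprintf("%s_vs_%s", ct[["case"]], ct[["control"]])
    screening[[nm]] <- screen_features(features, scr_feats, ct[["case"]],
                                       ct[["control"]],
                                       orientations = orientations)
    delong[[nm]] <- delong_matrix(features, screening[[nm]]$feature,
                                  ct[["case"]], ct[["control"]],
                                  orientations = orientations)
  }

  corr_feats <- setdiff(cmp_feats, "updrs3")
  correlations <- dplyr::bind_rows(lapply(
    intersect(c("de_novo_pd", "early_pd"), groups_present),
    function(g) correlate_features(features, corr_feats, g)
  ))

  structure(list(
    features = features,
    outliers_by_kind = outliers_by_kind,
    outliers_pooled = dplyr::left_join(outliers_pooled,
                                       metadata[, c("subject_id", "group")],
                                       by = "subject_id"),
    comparisons = comparisons,
    screening = screening,
    delong = delong,
    correlations = correlations,
    config = list(policy = unclass(policy),
                  screen_features = scr_feats,
                  compare_features = cmp_feats,
                  contrasts = contrasts, posthoc = posthoc,
                  n_subjects = nrow(features), n_events = nrow(events))
  ), class = "keystroke_study")
}

#' @export
print.keystroke_study <- function(x, ...) {
  cat(sprintf("Keystroke biomarker study: %d subjects, %d contrasts\n",
              nrow(x$features), length(x$screening)))
  for (nm in names(x$screening)) {
    cat(sprintf("\n  %s:\n", nm))
    s <- x$screening[[nm]]
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-14s AUC %.3f (%.3f-%.3f)  sens %3d%%  spec %3d%%\n",
                  s$feature[i], s$auc[i], s$ci_low[i], s$ci_high[i],
                  s$sensitivity[i], s$specificity[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.keystroke_study <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$screening), function(nm) {
    dplyr::mutate(dplyr::select(x$screening[[nm]], -"result"),
                  contrast = nm, .before = 1)
  }))
}

#' @export
glance.keystroke_study <- function(x, ...) {
  tibble(n_subjects = x$config$n_subjects,
         n_events = x$config$n_events,
         n_contrasts = length(x$screening),
         n_features_screened = length(x$config$screen_features),
         mean_pct_removed = mean(x$outliers_pooled$pct_removed))
}

#' @export
autoplot.keystroke_study <- function(object, ...) {
  roc_all <- dplyr::bind_rows(lapply(names(object$screening), function(nm) {
    s <- object$screening[[nm]]
    dplyr::bind_rows(lapply(s$result, tidy)) |>
      dplyr::mutate(contrast = nm)
  }))
  ggplot2::ggplot(roc_all,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity,
                               colour = .data$feature)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Feature") +
    ggplot2::theme_minimal()
}

#' Plot per-subject outlier removal percentages
#'
#' @param study A [run_study()] result.
#' @return A ggplot.
#' @export
plot_outlier_report <- function(study) {
  ggplot2::ggplot(study$outliers_pooled,
                  ggplot2::aes(x = .data$group, y = .data$pct_removed)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "Time points removed (%)") +
    ggplot2::theme_minimal()
}

#' Write all study reports to a directory
#'
#' Emits `features.csv`, `outlier_report.csv` (per kind) and
#' `outlier_report_pooled.csv`, `group_comparisons.csv`,
#' `screening_<contrast>.csv` and `delong_<contrast>.csv` per contrast,
#' `correlations.csv`, and a `manifest.json` capturing the resolved
#' configuration and row counts. Reports are schema-checked before writing;
#' missing values stay empty fields.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, required) {
    stopifnot_cols(df, required, name)
    readr::write_csv(df, file.path(dir, name), na = "")
    nrow(df)
  }
  counts <- list(
    features = w(study$features, "features.csv", c("subject_id", "il_sd")),
    outlier_report = w(study$outliers_by_kind, "outlier_report.csv",
                       c("subject_id", "kind", "n_input", "pct_removed")),
    outlier_report_pooled = w(study$outliers_pooled,
                              "outlier_report_pooled.csv",
                              c("subject_id", "pct_removed")),
    group_comparisons = w(study$comparisons, "group_comparisons.csv",
                          c("feature", "kw_p")),
    correlations = w(study$correlations, "correlations.csv",
                     c("feature", "group", "rho", "p", "n"))
  )
  for (nm in names(study$screening)) {
    counts[[paste0("screening_", nm)]] <-
      w(dplyr::select(study$screening[[nm]], -"result"),
        sprintf("screening_%s.csv", nm),
        c("feature", "auc", "ci_low", "ci_high", "cutoff",
          "sensitivity", "specificity"))
    counts[[paste0("delong_", nm)]] <-
      w(study$delong[[nm]], sprintf("delong_%s.csv", nm),
        c("feature_a", "feature_b", "z", "p"))
  }
  manifest <- list(package = "keyfluc",
                   version = as.character(utils::packageVersion("keyfluc")),
                   config = study$config, rows = counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
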