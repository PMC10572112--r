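feat_tbl <- function(cases, controls, feature = "il_sd") {
  d <- tibble::tibble(
    subject_id = paste0("S", seq_len(length(cases) + length(controls))),
    group = rep(c("de_novo_pd", "control"),
                c(length(cases), length(controls)))
  )
  d[[feature]] <- c(cases, controls)
  d
}

test_that("ROC staircase: perfect separation reaches sens = spec = 100%,
           the 2x2 fixture gives AUC 0.75, all-ties give 0.5", {
  s <- screen_feature(feat_tbl(c(3, 4), c(1, 2)), "il_sd",
                      "de_novo_pd", "control")
  expect_true(any(s$roc$sensitivity == 1 & s$roc$specificity == 1))
  expect_equal(s$auc, 1)

  s2 <- screen_feature(feat_tbl(c(2, 4), c(1, 3)), "il_sd",
                       "de_novo_pd", "control")
  expect_equal(s2$auc, 0.75)                  # 3 of 4 pairs concordant

  s3 <- screen_feature(feat_tbl(c(1, 1), c(1, 1)), "il_sd",
                       "de_novo_pd", "control")
  expect_equal(s3$auc, 0.5)                   # ties counted one half

  expect_error(screen_feature(feat_tbl(numeric(0), c(1, 2)), "il_sd",
                              "de_novo_pd", "control"))
})

test_that("trapezoid AUC equals exhaustive pair counting; complementing the
           scores complements the AUC; rank invariance holds", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n1 <- sample(1:15, 1)
      n0 <- sample(1:15, 1)
      cases <- sample(1:10, n1, replace = TRUE) + runif(n1) * (i %% 2)
      controls <- sample(1:10, n0, replace = TRUE) + runif(n0) * (i %% 2)
      roc <- keyfluc:::roc_points_core(cases, controls)
      auc_t <- keyfluc:::trapezoid_auc(roc)
      auc_r <- keyfluc:::auc_mw(cases, controls)
      expect_equal(auc_t, oracle_auc_pairs(cases, controls),
                   tolerance = 1e-12)
      expect_equal(auc_r, auc_t, tolerance = 1e-12)
      expect_equal(keyfluc:::auc_mw(-cases, -controls), 1 - auc_r,
                   tolerance = 1e-12)
      expect_equal(keyfluc:::auc_mw(exp(cases), exp(controls)), auc_r)
    }
  })
})

test_that("exact binomial CI matches the closed form at perfect separation
           and brackets the point estimate", {
  d <- feat_tbl(c(6, 7, 8, 9, 10), c(1, 2, 3, 4, 5))
  s <- screen_feature(d, "il_sd", "de_novo_pd", "control")
  expect_equal(s$auc_ci95[["lower"]], 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(s$auc_ci95[["upper"]], 1)

  s2 <- screen_feature(feat_tbl(c(2, 4), c(1, 3)), "il_sd",
                       "de_novo_pd", "control")
  expect_lte(s2$auc_ci95[["lower"]], s2$auc)
  expect_gte(s2$auc_ci95[["upper"]], s2$auc)
})

test_that("AUC and DeLong p agree with pROC on a fixture", {
  withr::with_seed(33, {
    labels <- rep(c(1, 0), c(12, 15))
    a <- c(rnorm(12, 1), rnorm(15))
    b <- 0.4 * a + rnorm(27)
    d <- tibble::tibble(subject_id = paste0("S", 1:27),
                        group = ifelse(labels == 1, "de_novo_pd", "control"),
                        fa = a, fb = b)
    s <- screen_feature(d, "fa", "de_novo_pd", "control",
                        orientation = "cases_higher")
    ra <- pROC::roc(labels, a, direction = "<", quiet = TRUE)
    expect_equal(s$auc, as.numeric(pROC::auc(ra)))
    dl <- delong_test(d, "fa", "fb", "de_novo_pd", "control",
                      orientations = c(fa = "cases_higher",
                                       fb = "cases_higher"))
    rb <- pROC::roc(labels, b, direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(dl$p, as.numeric(ref$p.value), tolerance = 1e-10)
  })
})

test_that("DeLong matches an independent placement-value computation and is
           degenerate-safe", {
  withr::with_seed(35, {
    xa_cases <- rnorm(5, 1)
    xa_controls <- rnorm(5)
    xb_cases <- rnorm(5, 0.5)
    xb_controls <- rnorm(5)
    d <- tibble::tibble(subject_id = paste0("S", 1:10),
                        group = rep(c("de_novo_pd", "control"), each = 5),
                        fa = c(xa_cases, xa_controls),
                        fb = c(xb_cases, xb_controls))
    dl <- delong_test(d, "fa", "fb", "de_novo_pd", "control",
                      orientations = c(fa = "cases_higher",
                                       fb = "cases_higher"))
    ref <- oracle_delong(xa_cases, xa_controls, xb_cases, xb_controls)
    expect_equal(dl$z, ref$z, tolerance = 1e-10)
    expect_equal(dl$p, ref$p, tolerance = 1e-10)

    same <- delong_test(d, "fa", "fa", "de_novo_pd", "control",
                        orientations = c(fa = "cases_higher"))
    expect_equal(same$p, 1)
    expect_equal(same$auc_a - same$auc_b, 0)
  })
})

test_that("Youden cutoff maximises J with the documented tie-break", {
  # fixture: controls {1,3}, cases {2,4}; J = 0.5 at thresholds 1.5 and 3.5,
  # the tie resolves to the higher-sensitivity point at 1.5
  s <- screen_feature(feat_tbl(c(2, 4), c(1, 3)), "il_sd",
                      "de_novo_pd", "control")
  expect_equal(s$cutoff, 1.5)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 0.5)

  # degenerate all-equal scores: J = 0 everywhere
  s0 <- screen_feature(feat_tbl(c(1, 1), c(1, 1)), "il_sd",
                       "de_novo_pd", "control")
  expect_equal(s0$youden, 0)

  withr::with_seed(37, {
    for (i in 1:200) {
      cases <- sample(1:8, sample(2:10, 1), replace = TRUE)
      controls <- sample(1:8, sample(2:10, 1), replace = TRUE)
      roc <- keyfluc:::roc_points_core(cases, controls)
      yc <- youden_cutoff(roc)
      expect_equal(yc$youden, oracle_max_youden(cases, controls),
                   tolerance = 1e-12)
    }
  })
})

test_that("orientation: the direction map flips low-running features and
           unknown features auto-orient with a message", {
  d <- feat_tbl(c(90, 95, 100), c(120, 130, 140), feature = "aftap")
  s <- screen_feature(d, "aftap", "de_novo_pd", "control")
  expect_equal(s$orientation, "cases_lower")
  expect_equal(s$auc, 1)                      # patients tap slower
  expect_lt(s$cutoff, 120)
  expect_gt(s$cutoff, 100)

  d2 <- feat_tbl(c(1, 2), c(3, 4), feature = "mystery")
  expect_message(s2 <- screen_feature(d2, "mystery", "de_novo_pd", "control"),
                 "auto-orienting")
  expect_equal(s2$auc, 1)
})

test_that("missing scores are dropped for that feature only, with counts", {
  d <- feat_tbl(c(1.3, 1.4, NA), c(1.0, 1.1, 1.2))
  s <- screen_feature(d, "il_sd", "de_novo_pd", "control")
  expect_equal(s$n_cases, 2)
  expect_equal(s$n_missing_dropped, 1)
})
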