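test_that("Spearman: monotone and antitone give +/-1, the tied example
           matches the hand computation, identities hold", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$rho, -1)
  # ranks x = (1, 2.5, 2.5, 4), y = (1, 3, 2, 4): rho = 4.5 / sqrt(22.5)
  res <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(res$rho, 4.5 / sqrt(22.5))
  expect_equal(res$rho, 0.9487, tolerance = 1e-4)

  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      x <- sample(1:12, n, replace = TRUE)
      y <- sample(1:12, n, replace = TRUE) + 0.3 * x
      r <- spearman_cor(x, y)
      expect_equal(r$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
      if (!anyDuplicated(x) && !anyDuplicated(y)) {
        d2 <- sum((rank(x) - rank(y))^2)
        expect_equal(r$rho, 1 - 6 * d2 / (n * (n^2 - 1)), tolerance = 1e-12)
      }
    }
  })
})

test_that("Spearman p-values: exact enumeration for small n matches
           cor.test, t approximation for larger n; constants give NA", {
  withr::with_seed(43, {
    for (n in c(5, 6, 7)) {
      x <- sample(100, n)
      y <- sample(100, n)
      mine <- spearman_cor(x, y)
      ref <- cor.test(x, y, method = "spearman")
      expect_equal(mine$method, "exact permutation")
      expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    }
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30)
    mine <- spearman_cor(x, y)
    rho <- cor(rank(x), rank(y))
    tstat <- rho * sqrt(28 / (1 - rho^2))
    expect_equal(mine$p, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  })
  expect_message(res <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("Kruskal-Wallis omnibus is rank-based (invariant to monotone
           transforms) and the three group pairs are all reported", {
  withr::with_seed(45, {
    d <- tibble::tibble(
      group = rep(c("control", "de_novo_pd", "early_pd"), each = 12),
      il_sd = c(rnorm(12, 1.15, 0.1), rnorm(12, 1.30, 0.1),
                rnorm(12, 1.27, 0.1))
    )
    cmp <- compare_group_feature(d, "il_sd")
    d2 <- dplyr::mutate(d, il_sd = exp(il_sd))
    cmp2 <- compare_group_feature(d2, "il_sd")
    expect_equal(cmp$statistic, cmp2$statistic, tolerance = 1e-12)
    expect_equal(cmp$pairwise$p, cmp2$pairwise$p, tolerance = 1e-12)
    expect_equal(nrow(cmp$pairwise), 3)
    expect_setequal(
      paste(cmp$pairwise$group_a, cmp$pairwise$group_b),
      c("control de_novo_pd", "control early_pd", "de_novo_pd early_pd")
    )
    expect_true(all(cmp$pairwise$p > 0 & cmp$pairwise$p <= 1))
    # Dunn-Holm variant is available and agrees on direction
    cmpd <- compare_group_feature(d, "il_sd", posthoc = "dunn")
    expect_equal(nrow(cmpd$pairwise), 3)
  })
})

test_that("an empty or unusable group drops out: omnibus over the rest,
           its pairs reported missing", {
  d <- tibble::tibble(
    group = rep(c("control", "de_novo_pd", "early_pd"), c(10, 10, 1)),
    il_sd = c(rnorm(10, 1.1, 0.05), rnorm(10, 1.3, 0.05), 1.2)
  )
  cmp <- compare_group_feature(d, "il_sd")
  expect_equal(cmp$df, 1)
  expect_true(is.na(cmp$pairwise$p[cmp$pairwise$group_b == "early_pd"][1]))
  p_main <- cmp$pairwise$p[cmp$pairwise$group_a == "control" &
                             cmp$pairwise$group_b == "de_novo_pd"]
  expect_false(is.na(p_main))
})

test_that("correlation tables recover a built-in severity link and return
           missing for constant features", {
  withr::with_seed(47, {
    n <- 18
    updrs <- round(runif(n, 11, 40))
    speed <- 160 - 2 * updrs + rnorm(n, 0, 8)    # strong negative link
    d <- tibble::tibble(subject_id = paste0("E", 1:n), group = "early_pd",
                        updrs3 = updrs, typing_speed = speed,
                        flat = rep(1, n))
    out <- correlate_features(d, c("typing_speed", "flat"), "early_pd")
    expect_lt(out$rho[out$feature == "typing_speed"], -0.6)
    expect_true(is.na(out$rho[out$feature == "flat"]))
    expect_equal(out$n, c(n, n))
  })
  expect_error(correlate_features(
    tibble::tibble(group = "early_pd", updrs3 = c(1, NA, NA), x = 1:3),
    "x", "early_pd"), "fewer than 3")
})
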