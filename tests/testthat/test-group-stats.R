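test_that("hedges_g matches hand arithmetic and is antisymmetric", {
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 4)), -0.8, tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(3)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(hedges_g(x, y), -hedges_g(y, x), tolerance = 1e-12)
  expect_error(hedges_g(1, c(1, 2)), ">= 2")
})

test_that("scene-blocked ANOVA matches an independent sums-of-squares oracle", {
  # balanced toy: 2 groups x 4 participants x 3 scenes
  set.seed(7)
  d <- expand.grid(participant_id = paste0("p", 1:8), scene_id = paste0("s", 1:3))
  d$group <- ifelse(d$participant_id %in% paste0("p", 1:4), "A", "B")
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "B", 0.7, 0) +
    rep(c(0, 0.5, -0.5), each = 8)
  res <- mixed_rm_anova(d)
  # oracle: explicit projection sums of squares for value ~ scene + group
  grand <- mean(d$value)
  ss_scene <- sum(tapply(d$value, d$scene_id, function(v) length(v) * (mean(v) - grand)^2))
  ss_group <- sum(tapply(d$value, d$group, function(v) length(v) * (mean(v) - grand)^2))
  fit_full <- lm(value ~ factor(scene_id) + factor(group), d)
  ss_res <- sum(residuals(fit_full)^2)
  df_den <- nrow(d) - 1 - 2 - 1
  F_oracle <- (ss_group / 1) / (ss_res / df_den)
  expect_equal(res$F, F_oracle, tolerance = 1e-9)
  expect_equal(res$eta_p2, ss_group / (ss_group + ss_res), tolerance = 1e-9)
  expect_equal(res$df_num, 1); expect_equal(res$df_den, df_den)
  expect_equal(nrow(res$posthoc), 1)
  expect_equal(res$posthoc$p_bonferroni, min(1, res$posthoc$p_raw))
})

test_that("ANOVA machinery validates its inputs", {
  d <- data.frame(participant_id = "p1", group = "A", scene_id = "s1",
                  value = 1)
  expect_error(mixed_rm_anova(d), "2 groups")
  d2 <- data.frame(participant_id = rep(c("p1", "p2"), 2),
                   group = rep(c("A", "B"), 2),
                   scene_id = c("s1", "s1", "s2", "s3"), value = rnorm(4))
  expect_error(mixed_rm_anova(d2), "cells")
})

test_that("two-way mixed ANOVA detects a group x stratum interaction", {
  set.seed(21)
  make2 <- function(gap) {
    d <- expand.grid(participant_id = paste0("p", 1:24),
                     stratum = c("few", "many"))
    d$group <- rep(rep(c("CU", "AD", "LBD"), each = 8), 2)
    d$value <- rnorm(nrow(d), 0, 0.5) +
      ifelse(d$stratum == "many" & d$group != "LBD", gap, 0)
    d
  }
  d <- make2(1.5)
  res <- two_way_interaction(d)
  expect_lt(res$p_interaction, 0.05)
  # symmetric relabeling of strata leaves F unchanged
  d$stratum <- ifelse(d$stratum == "few", "zz_few", "aa_many")
  expect_equal(two_way_interaction(d)$F_interaction, res$F_interaction,
               tolerance = 1e-9)
  expect_error(two_way_interaction(data.frame(
    participant_id = "p", group = c("A", "B"), stratum = "s",
    value = 1:2)), "2 levels")
})

test_that("per-scene effect sizes track object count when built to", {
  set.seed(5)
  counts <- setNames(sample(2:12, 20, replace = TRUE), paste0("s", 1:20))
  rows <- do.call(rbind, lapply(names(counts), function(sc) {
    sep <- 0.12 * counts[[sc]]  # separation grows with object count
    data.frame(scene_id = sc, group = rep(c("CU", "AD"), each = 10),
               value = rnorm(20) + rep(c(0, sep), each = 10))
  }))
  res <- per_image_effect_trend(rows, counts)
  expect_true(all(res$per_scene$eta_p2 >= 0 & res$per_scene$eta_p2 <= 1))
  expect_gt(res$r, 0.3)
})

test_that("partial Spearman removes a shared confound", {
  set.seed(9)
  n <- 200
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                     education = rnorm(n))
  # no covariate association: matches plain Spearman closely
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  ps <- partial_spearman(x, y, covs)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 0.02)
  # both driven solely by the confound -> near zero after adjustment
  z <- rnorm(n)
  x2 <- z + 0.1 * rnorm(n); y2 <- z + 0.1 * rnorm(n)
  covs2 <- data.frame(age = z, sex = rbinom(n, 1, 0.5), education = rnorm(n))
  expect_lt(abs(partial_spearman(x2, y2, covs2)$rho), 0.15)
  expect_error(partial_spearman(rep(1, n), y, covs), "constant")
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("forward stepwise BIC finds the true predictor and keeps covariates", {
  set.seed(13)
  n <- 50
  d <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                  education = rnorm(n))
  for (j in 1:10) d[[paste0("x", j)]] <- rnorm(n)
  d$resp <- 1.2 * d$x3 + 0.3 * d$age + rnorm(n)
  fit <- forward_stepwise_bic(d, "resp", paste0("x", 1:10))
  expect_true("x3" %in% fit$selected)
  expect_true(all(c("age", "sex", "education") %in%
                    attr(terms(fit$model), "term.labels")))
  # pure-noise candidates: usually nothing enters
  d$resp2 <- rnorm(n)
  fit2 <- forward_stepwise_bic(d, "resp2", paste0("x", 1:10))
  expect_lte(length(fit2$selected), 2)
  expect_true(all(diff(fit$bic_trace) < 0))
})

test_that("ANOVA power analysis reproduces the design sample size", {
  expect_identical(anova_power_n(0.5, 3, 0.05, 0.8), 14L)
  # bracketing: power(n-1) < target <= power(n)
  expect_lt(anova_power(0.5, 3, 13), 0.8)
  expect_gte(anova_power(0.5, 3, 14), 0.8)
  # boundary and monotonicity
  expect_identical(anova_power_n(0.5, 3, 0.05, 1e-9), 2L)
  ns <- vapply(c(0.3, 0.5, 0.8), anova_power_n, integer(1), k = 3)
  expect_true(all(diff(ns) < 0))
  expect_error(anova_power_n(-1, 3), "f > 0")
})

test_that("pupil fatigue test splits halves by stimulus index", {
  set.seed(31)
  d <- expand.grid(participant_id = paste0("p", 1:12), scene_index = 1:20)
  d$group <- rep(rep(c("CU", "AD"), each = 6), 20)
  d$pupil_mm <- rnorm(nrow(d), 3.5, 0.1)
  res <- pupil_fatigue_test(d)
  expect_true(res$p_interaction > 0.001)
  # one group with a strong late-session drop is detected
  d2 <- d
  drop_rows <- d2$group == "AD" & d2$scene_index > 10
  d2$pupil_mm[drop_rows] <- d2$pupil_mm[drop_rows] - 1
  expect_lt(pupil_fatigue_test(d2)$p_interaction, 0.01)
  expect_error(pupil_fatigue_test(d[, -4]), "pupil")
})
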