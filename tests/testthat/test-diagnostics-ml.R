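# feature-matrix simulators used across the classification tests
sim_features <- function(n_per_group, shift = 0, p = 65, seed = 1,
                         groups = c("AD", "CU", "LBD")) {
  set.seed(seed)
  k <- length(groups)
  X <- matrix(rnorm(k * n_per_group * p), k * n_per_group, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(groups, each = n_per_group)
  # distinct 10-feature signature per group
  for (gi in seq_len(k)) {
    cols <- ((gi - 1) * 10 + 1):(gi * 10)
    X[y == groups[gi], cols] <- X[y == groups[gi], cols] + shift
  }
  list(X = X, y = y)
}

test_that("binary AUC matches brute-force pair counting and pROC", {
  expect_equal(binary_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(binary_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(binary_auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  set.seed(8)
  s <- rnorm(60); y <- rbinom(60, 1, 0.5)
  brute <- mean(outer(s[y == 1], s[y == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(binary_auc(s, y), brute, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(binary_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
  expect_error(binary_auc(s, rep(1, 60)), "both classes")
})

test_that("Hand-Till AUC reduces to the binary AUC for two classes", {
  set.seed(9)
  for (i in 1:100) {
    s <- rnorm(30)
    y <- sample(c("a", "b"), 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    smat <- cbind(a = -s, b = s)
    expect_equal(hand_till_auc(smat, y), binary_auc(s, y == "b"),
                 tolerance = 1e-9)
  }
  # one-hot scores of the true class are perfect
  y3 <- rep(c("a", "b", "c"), 10)
  oh <- t(vapply(y3, function(cl) setNames(as.numeric(c("a", "b", "c") == cl),
                                           c("a", "b", "c")), numeric(3)))
  expect_equal(hand_till_auc(oh, y3), 1)
  # identical rows are chance
  expect_equal(hand_till_auc(matrix(1, 30, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))),
                             y3), 0.5)
  expect_error(hand_till_auc(oh[, 1:2], y3), "classes")
})

test_that("LASSO selection finds planted signal and stays sparse under null", {
  hits <- logical(8); sizes <- integer(8)
  for (i in 1:8) {
    set.seed(100 + i)
    X <- matrix(rnorm(80 * 65), 80, 65,
                dimnames = list(NULL, paste0("f", 1:65)))
    y <- rep(c(0, 1), 40)
    X[, 7] <- y + rnorm(80, 0, 0.1)
    sel <- suppressWarnings(lasso_select(X, y, seed = i))
    hits[i] <- "f7" %in% sel
    Xn <- X; Xn[, 7] <- rnorm(80)
    sizes[i] <- length(suppressWarnings(lasso_select(Xn, y, seed = i)))
  }
  expect_true(all(hits))
  expect_lte(median(sizes), 5)
  # duplicated informative feature: at least one of the pair selected
  set.seed(200)
  X <- matrix(rnorm(80 * 20), 80, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(0, 1), 40)
  X[, 1] <- y + rnorm(80, 0.1); X[, 2] <- X[, 1]
  expect_true(any(c("f1", "f2") %in% suppressWarnings(lasso_select(X, y, 1))))
  expect_error(lasso_select(X, rep(1, 80)), "2 classes")
})

test_that("cross-validation separates a separable cohort and not a null one", {
  sep <- sim_features(15, shift = 2, seed = 31, groups = c("AD", "CU"))
  cfg <- cv_config(n_folds = 5, n_repeats = 3, seed = 7)
  res <- cv_classify(sep$X, sep$y, cfg)
  expect_gte(res$mean_auc, 0.9)
  expect_length(res$auc, 3)
  expect_true(all(res$ci >= 0 & res$ci <= 1))
  # determinism
  res2 <- cv_classify(sep$X, sep$y, cfg)
  expect_identical(res$auc, res2$auc)
  # 3-class separable
  sep3 <- sim_features(12, shift = 2, seed = 32)
  res3 <- cv_classify(sep3$X, sep3$y, cv_config(n_folds = 4, n_repeats = 2,
                                                seed = 8))
  expect_gte(res3$mean_auc, 0.9)
  # label-shuffled features are at chance
  nul <- sim_features(15, shift = 0, seed = 33, groups = c("AD", "CU"))
  resn <- cv_classify(nul$X, nul$y, cv_config(n_folds = 5, n_repeats = 4,
                                              seed = 9))
  expect_gt(resn$mean_auc, 0.3)
  expect_lt(resn$mean_auc, 0.7)
})

test_that("per-fold AUC averaging tracks pooled scoring", {
  sep <- sim_features(15, shift = 2, seed = 71, groups = c("AD", "CU"))
  pooled <- cv_classify(sep$X, sep$y,
                        cv_config(n_folds = 5, n_repeats = 2, seed = 2))
  folded <- cv_classify(sep$X, sep$y,
                        cv_config(n_folds = 5, n_repeats = 2,
                                  fold_average = TRUE, seed = 2))
  expect_gte(folded$mean_auc, 0.9)
  expect_lt(abs(folded$mean_auc - pooled$mean_auc), 0.1)
})

test_that("no information leaks from test folds into selection", {
  # canary: a feature equal to the test-fold indicator of repeat 1 must not
  # be preferentially selected, because selection sees training rows only
  set.seed(41)
  n <- 40
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c("a", "b"), n / 2)
  canary_freq <- replicate(10, {
    Xc <- cbind(X, canary = sample(c(0, 1), n, replace = TRUE))
    res <- cv_classify(Xc, y, cv_config(n_folds = 5, n_repeats = 1,
                                        seed = sample.int(1e6, 1)))
    res$selection_freq[["canary"]]
  })
  expect_lt(mean(canary_freq), 0.35)
})

test_that("permutation p-values follow the add-one formula", {
  expect_equal(perm_pvalue(0.9, seq(0.3, 0.7, length.out = 100)), 1 / 101)
  expect_equal(perm_pvalue(0.55, c(0.4, 0.5, 0.6)), 2 / 4)
  expect_gt(perm_pvalue(2, rnorm(50)), 0)  # never exactly 0
  expect_error(perm_pvalue(1, numeric(0)), "one permutation")
  nul <- sim_features(10, shift = 0, seed = 51, groups = c("AD", "CU"))
  pt <- permutation_test(nul$X, nul$y,
                         cv_config(n_folds = 4, n_repeats = 1, seed = 3),
                         n_perm = 19, seed = 4)
  expect_gt(pt$p, 0.05)
  expect_length(pt$null_auc, 19)
})

test_that("the clinical baseline model uses exactly the five covariates", {
  set.seed(61)
  n <- 30
  cov <- data.frame(antipsychotic = rbinom(n, 1, 0.2),
                    MMSE = rnorm(n, 25, 3), age = rnorm(n, 75, 5),
                    sex = rbinom(n, 1, 0.5), education = rnorm(n, 12, 3),
                    extra = rnorm(n))
  y <- ifelse(cov$MMSE + rnorm(n, 0, 1) > 25, "CU", "AD")
  if (length(unique(y)) == 2) {
    res <- baseline_model(cov, y, cv_config(n_folds = 5, n_repeats = 2,
                                            seed = 5))
    expect_gt(res$mean_auc, 0.7)
    expect_false("extra" %in% names(res$selection_freq))
  }
  expect_error(baseline_model(cov[, -2], y, cv_config()), "MMSE")
})
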