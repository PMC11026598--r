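geom <- test_geometry()

test_that("location sampling respects the percentile sets and ties", {
  m <- matrix(1:100 / 5050, 10, 10)  # 100 distinct values
  locs <- sample_locations(m, n_per_class = 5, seed = 1)
  vals <- m[cbind(locs$y + 1, locs$x + 1)]
  expect_true(all(vals[locs$label == 1] >= sort(as.numeric(m))[91]))
  expect_true(all(vals[locs$label == -1] <= sort(as.numeric(m))[30]))
  # fixed seed reproduces the draw
  expect_identical(locs, sample_locations(m, n_per_class = 5, seed = 1))
  # degenerate map: warning and NULL
  expect_warning(out <- sample_locations(matrix(1, 10, 10), seed = 1),
                 "degenerate")
  expect_null(out)
  # candidate set smaller than requested: all returned with warning
  expect_warning(big <- sample_locations(m, n_per_class = 50, seed = 1),
                 "using all")
  expect_equal(sum(big$label == 1), 10)
})

test_that("training sets standardize and drop constant features", {
  set.seed(2)
  X <- cbind(a = rnorm(40), b = rnorm(40), c = rep(1, 40))
  y <- rep(c(1, -1), 20)
  expect_warning(ts <- make_training_set(X, y), "constant")
  expect_equal(unname(colMeans(ts$X)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(ts$X, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_identical(ts$dropped, "c")
  # idempotence: re-standardizing changes nothing
  ts2 <- make_training_set(ts$X, ts$y)
  expect_equal(ts2$X, ts$X, tolerance = 1e-9)
})

test_that("the fitted model recovers a planted center signal", {
  set.seed(3)
  stack <- test_stack(42, 5)
  # sample half the pixels near the image center so the center feature has
  # real variation, then define noiseless labels from its value
  H <- 120; W <- 160
  near <- which(center_map(c(H, W), test_geometry()) > 0.05)
  idx_lin <- c(sample(near, 200, replace = TRUE),
               sample(H * W, 200, replace = TRUE))
  idx <- cbind((idx_lin - 1) %% H + 1, (idx_lin - 1) %/% H + 1)
  cm <- stack$center[idx]
  y <- ifelse(cm > median(cm), 1, -1)
  X <- vapply(stack, function(m) m[idx], numeric(400))
  tr <- sample(400, 300)
  ts <- suppressWarnings(make_training_set(X[tr, ], y[tr]))
  aw <- fit_attention_model(ts)
  expect_equal(names(which.max(abs(aw$w))), "center")
  # held-out accuracy above 0.95
  Xte <- sweep(sweep(X[-tr, names(ts$center)], 2, ts$center), 2, ts$scale, "/")
  pred <- sign(drop(Xte %*% aw$w[names(ts$center)]) + aw$intercept)
  expect_gt(mean(pred == y[-tr]), 0.95)
})

test_that("pure-noise features give chance accuracy", {
  set.seed(4)
  aucs <- replicate(5, {
    X <- matrix(rnorm(200 * 8), 200, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c(1, -1), 100)
    ts <- make_training_set(X[1:150, ], y[1:150])
    aw <- fit_attention_model(ts)
    Xte <- sweep(sweep(X[151:200, ], 2, ts$center), 2, ts$scale, "/")
    mean(sign(drop(Xte %*% aw$w[colnames(X)]) + aw$intercept) == y[151:200])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("duplicated features share weight evenly and keep the decisions", {
  # an L2-regularized margin splits weight symmetrically across exact
  # duplicates; the induced classifications stay essentially unchanged
  set.seed(5)
  X <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sign(X[, 1] + 0.3 * rnorm(120)); y[y == 0] <- 1
  ts1 <- make_training_set(X, y)
  aw1 <- fit_attention_model(ts1)
  Xd <- cbind(X, f1b = X[, 1])
  ts2 <- make_training_set(Xd, y)
  aw2 <- fit_attention_model(ts2)
  expect_equal(aw2$w[["f1"]], aw2$w[["f1b"]], tolerance = 1e-6)
  s1 <- drop(ts1$X %*% aw1$w[colnames(X)]) + aw1$intercept
  s2 <- drop(ts2$X %*% aw2$w[colnames(Xd)]) + aw2$intercept
  expect_gt(mean(sign(s1) == sign(s2)), 0.98)
  expect_gt(cor(s1, s2), 0.99)
  expect_error(fit_attention_model(make_training_set(X, rep(1, 120))),
               "single class")
})

test_that("type contributions aggregate the documented groups", {
  w <- setNames(numeric(22), feature_map_names())
  w[highlevel_names()] <- 1
  expect_equal(type_contributions(w),
               c(center = 0, background = 0, low_level = 0, high_level = 1))
  expect_equal(type_contributions(setNames(numeric(22), feature_map_names())),
               c(center = 0, background = 0, low_level = 0, high_level = 0))
  w2 <- w; w2["center"] <- 3; w2[c("color", "intensity", "orientation")] <- c(1, 2, 3)
  tc <- type_contributions(w2)
  expect_equal(tc[["center"]], 3)
  expect_equal(tc[["low_level"]], 2)
  expect_equal(type_contributions(w2, method = "sum")[["low_level"]], 6)
})

test_that("group analysis equals the single-unit fit in the reduction case", {
  dm <- small_cohort_maps()
  stacks <- small_cohort_stacks()
  pid <- names(dm$maps)[1]
  sid <- names(Filter(Negate(is.null), dm$maps[[pid]]))[1]
  one <- list(); one[[pid]] <- dm$maps[[pid]][sid]
  res <- suppressWarnings(
    group_attention_analysis(one, dm$groups, stacks[sid],
                             level = "participant", min_scenes = 1, seed = 9))
  # oracle: direct pipeline on that scene's samples
  locs <- sample_locations(dm$maps[[pid]][[sid]],
                           seed = str_seed(pid, sid, base = 9))
  X <- extract_features(stacks[[sid]], locs)
  ts <- suppressWarnings(make_training_set(X, locs$label))
  aw <- fit_attention_model(ts)
  expect_equal(res[[pid]]$weights$w, aw$w, tolerance = 1e-9)
  # permutation invariance: participant order does not change group weights
  two_ids <- names(dm$maps)[1:2]
  g1 <- suppressWarnings(group_attention_analysis(
    dm$maps[two_ids], dm$groups, stacks, level = "group", seed = 4))
  g2 <- suppressWarnings(group_attention_analysis(
    dm$maps[rev(two_ids)], dm$groups, stacks, level = "group", seed = 4))
  expect_equal(g1[[1]]$weights$w, g2[[1]]$weights$w, tolerance = 1e-9)
})

test_that("participants with too few usable scenes are excluded", {
  dm <- small_cohort_maps()
  stacks <- small_cohort_stacks()
  expect_warning(
    res <- group_attention_analysis(dm$maps[1], dm$groups, stacks,
                                    level = "participant", min_scenes = 100),
    "excluded")
  expect_length(res, 0)
})
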