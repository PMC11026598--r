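geom <- test_geometry()

test_that("ROI masks partition the image and allow attribute overlap", {
  sc <- test_scene(42, 5)
  rois <- roi_masks(sc)
  expect_length(rois, 15)
  expect_identical(names(rois), roi_names())
  total <- rois$semantic_objects + rois$other_objects + rois$background
  expect_true(all(total == 1))  # exact partition
  expect_false(any(rois$semantic_objects & rois$background))
  # a no-semantics scene puts every object into other_objects
  sc0 <- test_scene(42, 5)
  for (i in seq_along(sc0$objects)) sc0$objects[[i]]$semantics[] <- 0
  r0 <- roi_masks(sc0)
  expect_false(any(r0$semantic_objects))
  expect_identical(r0$other_objects, object_union_mask(sc0))
  # an object with two flags is counted in both attribute masks
  sc2 <- test_scene(42, 5)
  sc2$objects[[1]]$semantics[] <- 0
  sc2$objects[[1]]$semantics[c("face", "text")] <- 1
  r2 <- roi_masks(sc2)
  expect_true(any(r2$face & r2$text))
})

test_that("gaze proportions count samples in ROIs", {
  sc <- test_scene(42, 5)
  rois <- roi_masks(sc)
  # all samples on background
  bg <- which(rois$background, arr.ind = TRUE)[1:30, ]
  pts <- data.frame(t_s = (0:29) / 60, x_px = bg[, 2] - 1, y_px = bg[, 1] - 1)
  pr <- roi_gaze_proportions(pts, rois)
  expect_equal(pr[["background"]], 1)
  expect_equal(pr[["semantic_objects"]] + pr[["other_objects"]], 0)
  # half the samples in one object
  ob <- which(sc$objects[[1]]$mask, arr.ind = TRUE)[1:30, ]
  pts2 <- data.frame(t_s = (0:59) / 60,
                     x_px = c(bg[, 2], ob[, 2]) - 1,
                     y_px = c(bg[, 1], ob[, 1]) - 1)
  pr2 <- roi_gaze_proportions(pts2, rois)
  on_obj <- pr2[["semantic_objects"]] + pr2[["other_objects"]]
  expect_equal(on_obj, 0.5)
  expect_equal(pr2[["background"]] + on_obj, 1, tolerance = 1e-9)
  expect_error(roi_gaze_proportions(pts[0, ], rois), "skipped")
})

test_that("partition conservation holds on generated recordings", {
  co <- small_cohort()
  dm <- small_cohort_maps()
  rois <- lapply(co$scenes, roi_masks)
  checked <- 0
  for (pid in names(dm$clean)[1:3]) for (sid in names(dm$clean[[pid]])) {
    cg <- dm$clean[[pid]][[sid]]
    if (nrow(cg$points) == 0) next
    pr <- roi_gaze_proportions(cg$points, rois[[sid]])
    expect_equal(pr[["semantic_objects"]] + pr[["other_objects"]] +
                   pr[["background"]], 1, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("density-mass proportions also conserve the partition", {
  co <- small_cohort()
  dm <- small_cohort_maps()
  pid <- names(dm$maps)[1]
  sid <- names(Filter(Negate(is.null), dm$maps[[pid]]))[1]
  rois <- roi_masks(co$scenes[[sid]])
  pr <- roi_gaze_proportions(method = "density", rois = rois,
                             map = dm$maps[[pid]][[sid]], points = NULL)
  expect_equal(pr[["semantic_objects"]] + pr[["other_objects"]] +
                 pr[["background"]], 1, tolerance = 1e-9)
  expect_error(roi_gaze_proportions(NULL, rois, method = "density"),
               "requires a density map")
})

test_that("visit durations follow run-length arithmetic", {
  sc <- test_scene(42, 5)
  rois <- roi_masks(sc)
  ob <- which(sc$objects[[1]]$mask, arr.ind = TRUE)[1, ]
  bg <- which(rois$background, arr.ind = TRUE)[1, ]
  # 180 consecutive in-ROI samples -> one 3 s visit
  pts <- data.frame(t_s = (0:179) / 60, x_px = rep(ob[2] - 1, 180),
                    y_px = rep(ob[1] - 1, 180))
  key <- if (sum(sc$objects[[1]]$semantics) > 0) "semantic_objects" else "other_objects"
  dv <- roi_visit_durations(pts, rois, 60)
  expect_equal(dv[[key]], 3)
  expect_true(attr(dv, "visited")[[key]])
  expect_false(attr(dv, "visited")[["background"]])
  expect_equal(dv[["background"]], 0)
  # alternating in/out every sample -> mean visit 1/60 s
  pts2 <- data.frame(t_s = (0:59) / 60,
                     x_px = rep(c(ob[2], bg[2]) - 1, 30),
                     y_px = rep(c(ob[1], bg[1]) - 1, 30))
  dv2 <- roi_visit_durations(pts2, rois, 60)
  expect_equal(dv2[[key]], 1 / 60, tolerance = 1e-9)
  # a time gap (dropped samples) splits a visit in two
  pts3 <- data.frame(t_s = c(0:9, 20:29) / 60, x_px = rep(ob[2] - 1, 20),
                     y_px = rep(ob[1] - 1, 20))
  dv3 <- roi_visit_durations(pts3, rois, 60)
  expect_equal(dv3[[key]], 10 / 60, tolerance = 1e-9)  # two 10-sample visits
  # total visit time never exceeds the viewing duration
  expect_true(all(dv[roi_names()] <= 3 + 1e-9))
})

test_that("the participant feature vector has the documented 65 entries", {
  tw <- c(center = 0.5, background = 0.1, low_level = 0.2, high_level = 0.9)
  P <- matrix(0.2, 3, 15); D <- matrix(0.1, 3, 15)
  V <- matrix(TRUE, 3, 15)
  fv <- participant_feature_vector(tw, c(10, 11, 12), P, D, V)
  expect_length(fv, 65)
  expect_identical(names(fv), eye_feature_names())
  # identical per-scene values -> all sd features 0
  expect_true(all(fv[grepl("_sd$", names(fv))] == 0))
  expect_equal(fv[["entropy_mean"]], 11)
  # hand-built 3-scene fixture with known proportions
  P2 <- P; P2[, 1] <- c(0.1, 0.2, 0.3)
  fv2 <- participant_feature_vector(tw, c(10, 11, 12), P2, D, V)
  expect_equal(fv2[["prop_face_mean"]], 0.2, tolerance = 1e-12)
  expect_equal(fv2[["prop_face_sd"]], sd(c(0.1, 0.2, 0.3)), tolerance = 1e-12)
  # never-visited ROI durations are excluded, not averaged as zeros
  D3 <- D; V3 <- V; V3[1:2, 2] <- FALSE; D3[1:2, 2] <- 0; D3[3, 2] <- 0.5
  fv3 <- participant_feature_vector(tw, c(10, 11, 12), P, D3, V3)
  expect_equal(fv3[[paste0("dur_", roi_names()[2], "_mean")]], 0)  # <2 scenes
  V3[2, 2] <- TRUE; D3[2, 2] <- 0.3
  fv4 <- participant_feature_vector(tw, c(10, 11, 12), P, D3, V3)
  expect_equal(fv4[[paste0("dur_", roi_names()[2], "_mean")]], 0.4)
  expect_error(participant_feature_vector(tw, 10, P[1, , drop = FALSE],
                                          D[1, , drop = FALSE],
                                          V[1, , drop = FALSE]),
               "fewer than 2")
})

test_that("cohort feature tables are complete per participant", {
  co <- small_cohort()
  feats <- suppressWarnings(suppressMessages(
    cohort_features(co, dm = small_cohort_maps(),
                    stacks = small_cohort_stacks())))
  expect_equal(sum(names(feats) %in% eye_feature_names()), 65)
  expect_true(all(table(feats$group) >= 1))
  expect_false(anyNA(feats[, eye_feature_names()]))
})
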