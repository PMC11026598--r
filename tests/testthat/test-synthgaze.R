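geom <- test_geometry()

test_that("scene generation is deterministic and honors the object count", {
  sc <- test_scene(42, 5)
  expect_s3_class(sc, "annotated_scene")
  expect_equal(sc$n_objects, 5)
  expect_length(sc$objects, 5)
  sc2 <- generate_scene(scene_config(160, 120, n_objects = 5, seed = 42),
                        scene_id = "scene_s42")
  expect_identical(sc, sc2)
  # empty scene: no objects, background everywhere
  sc0 <- generate_scene(scene_config(160, 120, n_objects = 0, seed = 1))
  expect_length(sc0$objects, 0)
  expect_true(all(background_map(sc0) == 1))
  # masks are non-empty and pairwise disjoint
  masks <- lapply(sc$objects, `[[`, "mask")
  expect_true(all(vapply(masks, sum, numeric(1)) >= 25))
  expect_lte(max(Reduce(`+`, lapply(masks, `*`, 1))), 1)
})

test_that("unplaced cohorts of scenes have median object count 7", {
  counts <- vapply(1:200, function(i) {
    cfg <- scene_config(160, 120, n_objects = NA, seed = 5000 + i)
    with_seed(cfg$seed, rpois(1, 7))  # the draw generate_scene would make
  }, numeric(1))
  expect_equal(median(counts), 7)
  # and a sample of fully generated scenes agrees with the drawn counts
  sc <- generate_scene(scene_config(160, 120, n_objects = NA, seed = 5001))
  expect_equal(sc$n_objects, counts[1])
})

test_that("object properties satisfy the closed-form shape identities", {
  pd <- compute_object_properties(disc_mask())
  expect_equal(pd$complexity, 1, tolerance = 0.05)
  expect_equal(pd$convexity, 1, tolerance = 0.05)
  expect_equal(pd$solidity, 1, tolerance = 0.05)
  expect_equal(pd$eccentricity, 0, tolerance = 0.05)
  # 2:1 ellipse eccentricity sqrt(3)/2
  pe <- compute_object_properties(ellipse_mask())
  expect_equal(pe$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  # star is less solid than its (convex) hull and has higher complexity
  p <- radial_polygon(120, 120, rep(c(70, 30), 5), 0.3)
  star <- raster_polygon(240, 240, p$x, p$y)
  ps <- compute_object_properties(star)
  expect_lt(ps$solidity, 0.7)
  expect_lt(ps$convexity, 1)
  expect_gt(ps$complexity, 1.5)
  expect_error(compute_object_properties(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(compute_object_properties(two), "components")
})

test_that("gaze simulation emits the contracted sample grid", {
  sc <- test_scene(42, 5)
  vp <- viewer_profile("t", 1, 0, 0, exploration = 1, jitter_sd_deg = 1e-9,
                       blink_rate_hz = 0)
  rec <- simulate_gaze(sc, vp, geom, duration_s = 3, rate_hz = 60, seed = 5)
  expect_equal(nrow(rec), 180)  # blink rate 0: exactly duration x rate
  expect_true(all(rec$valid == 1))
  # pure center viewer with no jitter: all samples within 3 sigma of center
  x <- (rec$lx_px + rec$rx_px) / 2; y <- (rec$ly_px + rec$ry_px) / 2
  r3 <- 3 * px_per_degree(geom)
  expect_true(all(sqrt((x - 79.5)^2 + (y - 59.5)^2) <= r3 + 1e-6))
  # binocular disparity is fixed and horizontal
  expect_equal(unique(round(rec$rx_px - rec$lx_px, 9)),
               round(0.4 * px_per_degree(geom), 9))
  expect_equal(rec$ly_px, rec$ry_px)
  # determinism
  rec2 <- simulate_gaze(sc, vp, geom, duration_s = 3, rate_hz = 60, seed = 5)
  expect_identical(unclass(rec), unclass(rec2))
  expect_error(simulate_gaze(sc, vp, geom, duration_s = 0), "positive")
  expect_error(simulate_gaze(sc, vp, geom, rate_hz = -1), "positive")
})

test_that("fixation mixture fractions converge to the profile weights", {
  sc <- test_scene(42, 5)
  vp <- viewer_profile("t", 0.3, 0.5, 0.2, exploration = 2)
  types <- character(0)
  for (s in 1:120) {
    rec <- simulate_gaze(sc, vp, geom, seed = 7000 + s)
    types <- c(types, attr(rec, "fixations")$type)
  }
  n <- length(types)
  expect_gt(n, 1000)
  w <- c(center = 0.3, object = 0.5, background = 0.2)
  for (k in names(w)) {
    se <- sqrt(w[[k]] * (1 - w[[k]]) / n)
    expect_lt(abs(mean(types == k) - w[[k]]), 3 * se + 0.02)
  }
})

test_that("exploration raises downstream map entropy", {
  sc <- test_scene(42, 5)
  ent <- function(expl, s) {
    vp <- viewer_profile("t", 0.2, 0.6, 0.2, exploration = expl)
    rec <- simulate_gaze(sc, vp, geom, seed = s)
    cg <- process_recording(rec, geom)
    map_entropy(density_map(cg$points, geom, px_per_degree(geom)))
  }
  lo <- vapply(1:12, function(s) ent(0.5, 100 + s), numeric(1))
  hi <- vapply(1:12, function(s) ent(2.5, 200 + s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("viewer profile invariants are enforced", {
  expect_error(viewer_profile(w_center = 0.5, w_object = 0.6,
                              w_background = 0), "sum to 1")
  expect_error(viewer_profile(exploration = 0), "positive")
  expect_error(viewer_profile(fixation_duration_mean_s = -1), "positive")
  p <- default_profiles()
  expect_named(p, c("CU", "AD", "LBD"))
  expect_gt(p$CU$exploration, p$LBD$exploration)
  expect_lt(p$CU$w_center, p$LBD$w_center)
})

test_that("cohort generation writes the full bundle with reproducible manifests", {
  spec <- cohort_spec(n_per_group = c(CU = 2, AD = 1), n_images = 3,
                      profiles = default_profiles(), geometry = geom,
                      seed = 77)
  d1 <- withr::local_tempdir()
  co <- generate_cohort(spec, d1)
  expect_length(list.files(file.path(d1, "gaze")), 3 * 3)  # 3 participants x 3
  expect_length(list.files(file.path(d1, "scenes"), pattern = "png$"), 3)
  expect_length(list.files(file.path(d1, "scenes"), pattern = "json$"), 3)
  expect_true(file.exists(file.path(d1, "participants.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # same master seed -> identical manifest
  d2 <- withr::local_tempdir()
  generate_cohort(spec, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # scene JSON round-trips masks and annotations
  sc <- co$scenes[[1]]
  back <- read_scene_json(file.path(d1, "scenes",
                                    paste0(sc$scene_id, ".json")))
  expect_equal(length(back$objects), length(sc$objects))
  expect_identical(back$objects[[1]]$mask, sc$objects[[1]]$mask)
  expect_equal(unname(back$objects[[1]]$centroid_xy_px),
               unname(sc$objects[[1]]$centroid_xy_px), tolerance = 1e-9)
})

test_that("metadata is group-conditioned", {
  co <- small_cohort()
  p <- co$participants
  expect_equal(nrow(p), 9)
  expect_true(all(brain_roi_names() %in% names(p)))
  expect_true(mean(p$MMSE[p$group == "CU"]) > mean(p$MMSE[p$group != "CU"]))
  expect_true(all(is.na(p$stage[p$group == "CU"])))
  expect_true(all(p$stage[p$group != "CU"] %in% c("MCI", "dementia")))
})
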