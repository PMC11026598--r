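# Shared fixtures: a small display geometry (same physical screen and
# distance as the reference setup, fewer pixels so maps stay fast) and
# cached small scenes/cohorts built once per test run.

test_geometry <- function(width_px = 160, height_px = 120) {
  screen_geometry(width_px = width_px, height_px = height_px,
                  width_cm = 40.64, height_cm = 30.48, distance_cm = 80)
}

# reference 1600x1200 display
full_geometry <- function() screen_geometry()

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_scene <- function(seed = 42, n_objects = 5) {
  cached(sprintf("scene_%d_%d", seed, n_objects),
         generate_scene(scene_config(160, 120, n_objects = n_objects,
                                     seed = seed),
                        scene_id = sprintf("scene_s%d", seed)))
}

test_stack <- function(seed = 42, n_objects = 5) {
  cached(sprintf("stack_%d_%d", seed, n_objects),
         suppressMessages(build_feature_stack(test_scene(seed, n_objects),
                                              test_geometry())))
}

small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(cohort_spec(n_per_group = c(CU = 3, AD = 3, LBD = 3),
                                     n_images = 6, geometry = test_geometry(),
                                     seed = 11)))
}

small_cohort_maps <- function() {
  cached("small_cohort_maps", cohort_density_maps(small_cohort()))
}

small_cohort_stacks <- function() {
  cached("small_cohort_stacks",
         suppressMessages(lapply(small_cohort()$scenes, build_feature_stack,
                                 geometry = test_geometry())))
}

# rasterized disc / ellipse masks for morphology oracles
disc_mask <- function(n = 240, r = 80) {
  xx <- col(matrix(0, n, n)); yy <- row(matrix(0, n, n))
  (xx - n / 2 - 0.5)^2 + (yy - n / 2 - 0.5)^2 <= r^2
}

ellipse_mask <- function(n = 240, a = 100, b = 50) {
  xx <- col(matrix(0, n, n)); yy <- row(matrix(0, n, n))
  ((xx - n / 2 - 0.5) / a)^2 + ((yy - n / 2 - 0.5) / b)^2 <= 1
}
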