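# Shared configuration for the analysis scripts: study-condition cohort
# (three diagnostic groups on a shared stimulus set) rendered at a reduced
# pixel grid of the reference display geometry. Source this from each
# numbered script.
suppressMessages(library(gazedem))

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

ANALYSIS_SEED <- 20260923L

analysis_geometry <- function()
  screen_geometry(width_px = 320, height_px = 240,
                  width_cm = 40.64, height_cm = 30.48, distance_cm = 80)

analysis_spec <- function()
  cohort_spec(n_per_group = c(CU = 14, AD = 14, LBD = 14), n_images = 20,
              geometry = analysis_geometry(), seed = ANALYSIS_SEED)

# cohort and derived maps are cached on disk under scratch/ (regenerated
# deterministically when absent)
analysis_cohort <- function() {
  f <- file.path(SCRATCH_DIR, "analysis_cohort.rds")
  if (file.exists(f)) return(readRDS(f))
  co <- simulate_cohort(analysis_spec())
  saveRDS(co, f)
  co
}

analysis_maps <- function(co = analysis_cohort()) {
  f <- file.path(SCRATCH_DIR, "analysis_maps.rds")
  if (file.exists(f)) return(readRDS(f))
  dm <- cohort_density_maps(co)
  saveRDS(dm, f)
  dm
}

analysis_stacks <- function(co = analysis_cohort()) {
  f <- file.path(SCRATCH_DIR, "analysis_stacks.rds")
  if (file.exists(f)) return(readRDS(f))
  st <- suppressMessages(lapply(co$scenes, build_feature_stack,
                                geometry = analysis_geometry()))
  saveRDS(st, f)
  st
}

entropy_long_table <- function(co = analysis_cohort(), dm = analysis_maps(co)) {
  rows <- list()
  for (pid in names(dm$maps)) for (sid in names(dm$maps[[pid]])) {
    m <- dm$maps[[pid]][[sid]]
    if (is.null(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = pid, group = dm$groups[[pid]], scene_id = sid,
      value = map_entropy(m))
  }
  do.call(rbind, rows)
}
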