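#!/usr/bin/env Rscript
# Map-level statistics on the simulated cohort: gaze similarity to controls,
# Shannon entropy of the gaze-density maps (scene-blocked repeated-measures
# ANOVA with Bonferroni post-hoc tests and Hedges' g), the object-count
# median-split interaction, the per-scene effect-size trend, the empty-center
# 2-degree bias check, and the pupil fatigue control analysis.
source("analysis/00_config.R")

co <- analysis_cohort()
dm <- analysis_maps(co)
geom <- analysis_geometry()

## gaze similarity to controls --------------------------------------------
sim <- similarity_to_controls(dm$maps, dm$groups, control = "CU")
cat("similarity to controls (group means):\n")
print(round(attr(sim, "group_summary"), 3))
sim_an <- mixed_rm_anova(sim, value = "r")
print(sim_an)
write.csv(sim, file.path(RESULTS_DIR, "similarity_to_controls.csv"),
          row.names = FALSE)

## entropy of gaze-density maps -------------------------------------------
ent <- entropy_long_table(co, dm)
cat("\nmap entropy (bits), group means:\n")
print(round(tapply(ent$value, ent$group, mean), 2))
ent_an <- mixed_rm_anova(ent)
print(ent_an)
write.csv(ent, file.path(RESULTS_DIR, "entropy_long.csv"), row.names = FALSE)
write.csv(ent_an$posthoc, file.path(RESULTS_DIR, "entropy_posthoc.csv"),
          row.names = FALSE)

## median split by object count -------------------------------------------
n_obj <- vapply(co$scenes, function(s) s$n_objects, numeric(1))
ent$stratum <- ifelse(n_obj[ent$scene_id] > median(n_obj),
                      "more_objects", "fewer_objects")
tw <- two_way_interaction(ent)
cat("\nobject-count split: interaction F =",
    round(tw$F_interaction, 2), ", p =", signif(tw$p_interaction, 3), "\n")
write.csv(tw$posthoc_stratum_within_group,
          file.path(RESULTS_DIR, "entropy_objectcount_posthoc.csv"),
          row.names = FALSE)

## per-scene effect size vs object count ----------------------------------
trend <- per_image_effect_trend(ent, n_obj)
cat("per-scene eta_p^2 vs object count: r =", round(trend$r, 3),
    ", p =", signif(trend$p, 3), "\n")
write.csv(trend$per_scene, file.path(RESULTS_DIR, "per_scene_effect.csv"),
          row.names = FALSE)

## empty-center (2 deg) center-bias check ---------------------------------
cds <- center_disc_stats(dm$maps, dm$groups, co$scenes, geom, radius_deg = 2)
cat("\nscenes with empty 2-degree center:", length(cds$eligible_scenes), "\n")
if (length(cds$eligible_scenes)) {
  cat("center gaze-density ratio vs CU:\n")
  print(round(cds$ratio_vs_control, 2))
  write.csv(cds$table, file.path(RESULTS_DIR, "center_disc_shares.csv"),
            row.names = FALSE)
}

## pupil fatigue control ---------------------------------------------------
pup <- do.call(rbind, lapply(names(co$recordings), function(pid) {
  recs <- co$recordings[[pid]]
  data.frame(participant_id = pid, group = dm$groups[[pid]],
             scene_index = seq_along(recs),
             pupil_mm = vapply(recs, function(r) mean(r$pupil_mm),
                               numeric(1)))
}))
pf <- pupil_fatigue_test(pup)
cat("\npupil fatigue: group p =", signif(pf$p_group, 3),
    "| group x half interaction p =", signif(pf$p_interaction, 3), "\n")
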