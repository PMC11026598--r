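#!/usr/bin/env Rscript
# Assemble the 65-dimensional eye-movement feature vector per participant
# (4 attention-type weights, mean map entropy, 15 ROI gaze-proportion
# means/sds, 15 ROI visit-duration means/sds) joined with the clinical
# covariates.
source("analysis/00_config.R")

co <- analysis_cohort()
feats <- suppressWarnings(suppressMessages(
  cohort_features(co, dm = analysis_maps(co), stacks = analysis_stacks(co),
                  n_per_class = 20, seed = ANALYSIS_SEED)))
cat("participants with complete features:", nrow(feats), "of",
    nrow(co$participants), "\n")
cat("eye-movement feature columns:",
    sum(names(feats) %in% eye_feature_names()), "\n")
on_obj <- feats$prop_semantic_objects_mean + feats$prop_other_objects_mean
cat("gaze-on-object proportion by group:\n")
print(round(tapply(on_obj, feats$group, mean), 3))
write.csv(feats, file.path(RESULTS_DIR, "participant_features.csv"),
          row.names = FALSE)
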