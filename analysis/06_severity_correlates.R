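#!/usr/bin/env Rscript
# Exploratory clinical-instrumental correlations within each patient group:
# covariate-adjusted Spearman correlations of the eye-movement summaries
# (mean entropy, high-level attention contribution, center contribution)
# with MMSE, CDR-SB and gait speed, BH correction across the family, and
# forward-stepwise BIC regressions on the 10 brain-ROI measures.
source("analysis/00_config.R")

feats <- read.csv(file.path(RESULTS_DIR, "participant_features.csv"))
measures <- c("entropy_mean", "w_high_level", "w_center")
clinical <- c("MMSE", "CDR_SB", "gait_speed")

rows <- list()
for (g in c("AD", "LBD")) {
  d <- feats[feats$group == g, ]
  covs <- d[, c("age", "sex", "education")]
  for (m in measures) for (cl in clinical) {
    ps <- partial_spearman(d[[m]], d[[cl]], covs)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, measure = m, clinical = cl, rho = ps$rho, p = ps$p,
      n = ps$n)
  }
}
cors <- do.call(rbind, rows)
cors$p_bh <- bh_adjust(cors$p)
cat("covariate-adjusted Spearman correlations (patients only):\n")
print(cbind(cors[1:4], round(cors[5:7], 3)))
write.csv(cors, file.path(RESULTS_DIR, "severity_correlations.csv"),
          row.names = FALSE)

cat("\nstepwise BIC regressions on brain ROIs:\n")
for (g in c("AD", "LBD")) for (m in measures) {
  d <- feats[feats$group == g, ]
  fit <- suppressWarnings(
    forward_stepwise_bic(d, m, brain_roi_names(),
                         forced = c("age", "sex", "education")))
  cat(g, "/", m, ": selected",
      if (length(fit$selected)) paste(fit$selected, collapse = ", ")
      else "(covariates only)", "\n")
}
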