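# gazedem

Free-viewing gaze analysis and visual-attention modelling for dementia
cohorts.

When people look at complex scenes with no task ("just look at the
images"), *where* they look is diagnostic: patients with Alzheimer's
disease (AD) and Lewy body disease (LBD) explore less of the scene, look
less at meaningful objects, and look more at the image center than
cognitively unimpaired (CU) viewers. gazedem implements the complete
computational pipeline for quantifying these effects from 60 Hz binocular
eye-tracking on annotated scenes, plus a synthetic-cohort generator so the
whole pipeline runs, and is testable, with no external recordings.

The pipeline measures, per participant:

* **Gaze-density maps** — gaze samples smoothed with a fovea-sized Gaussian
  (sigma 55 px at 1600 x 1200, ~1 deg) and normalized: `p(x)` with
  `sum p = 1`.
* **Exploration** — Shannon entropy `H = -sum_i p_i log2 p_i` (bits).
* **Similarity to controls** — Pearson correlation `r` between flattened
  density maps, averaged over all patient-control (or within-control)
  pairs.
* **Attention-bias weights** — a linear SVM trained to separate looked
  (top 10% of density values) from not-looked (bottom 30%) pixels by their
  values in 22 feature maps: image center, background, 3 Itti-Koch
  conspicuity maps (color / intensity / orientation) and 17 object-attribute
  maps (4 shape properties, 12 semantic attributes, object presence). The
  signed per-type means of the weights are the relative contributions of
  center / background / low-level / high-level features.
* **ROI gaze statistics** — proportions and mean visit durations on 15
  scene ROIs, giving (with the 4 type weights and mean entropy) a
  65-dimensional eye-movement feature vector.
* **Diagnosis classification** — stratified repeated k-fold CV with
  embedded LASSO selection and a linear SVM; binary AUC by ranks,
  three-class AUC by Hand-Till's `M = 2/(c(c-1)) sum_{i<j}
  [A(i|j)+A(j|i)]/2`; label-permutation significance.
* **Group statistics** — scene-blocked repeated-measures ANOVA with
  Bonferroni post-hoc tests and Hedges' g, two-way mixed designs,
  partial-eta-squared trends, covariate-adjusted Spearman correlations,
  BH correction, forward-stepwise BIC regression, and the noncentral-F
  power analysis (f = 0.5, alpha = 0.05, power 0.8, 3 groups -> n = 14 per
  group).

## Worked example

Simulate a small cohort (3 per group, 6 scenes), build density maps and
compare map entropy across groups:

```r
library(gazedem)

geom <- screen_geometry(width_px = 160, height_px = 120,
                        width_cm = 40.64, height_cm = 30.48,
                        distance_cm = 80)   # 28.5 x 21.6 deg, 5.6 px/deg
co <- simulate_cohort(cohort_spec(n_per_group = c(CU = 3, AD = 3, LBD = 3),
                                  n_images = 6, geometry = geom, seed = 11))
dm <- cohort_density_maps(co)

ent <- sapply(names(dm$maps), function(p)
  mean(sapply(Filter(Negate(is.null), dm$maps[[p]]), map_entropy)))
round(tapply(ent, dm$groups[names(ent)], mean), 2)
#>    AD    CU   LBD
#> 11.80 12.12 11.17
```

CU viewers disperse gaze most (highest entropy in bits over the 160 x 120
map), LBD least — the diminished-exploration ordering the synthetic presets
are built to reproduce. The attention model on the same cohort:

```r
stacks <- lapply(co$scenes, build_feature_stack, geometry = geom)
ga <- group_attention_analysis(dm$maps, dm$groups, stacks, level = "group")
round(t(sapply(ga, `[[`, "types")), 2)
#>     center background low_level high_level
#> CU    1.77      -0.58     -0.05       0.21
#> AD    2.64       0.07      0.03       0.15
#> LBD   2.59       0.01      0.16       0.09
```

Center contributions rise and high-level (object) contributions fall from
CU to the patient groups. At this toy scale the orderings are noisy; the
validation experiments average them over replicates
(`preset_type_contributions()`).

The full study-scale workflow (14 participants per group, 20 scenes,
classification and severity correlates) lives in the numbered scripts under
`analysis/`; run them in order from the repository root.

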