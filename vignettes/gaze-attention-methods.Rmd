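---
title: "Methods: free-viewing gaze analysis and attention modelling in gazedem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-viewing gaze analysis and attention modelling in gazedem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gazedem characterises spontaneous eye movements during free viewing of
annotated complex scenes in three diagnostic groups — cognitively unimpaired
(CU), Alzheimer's disease (AD) and Lewy body disease (LBD) — and asks whether
the spatial statistics of gaze, and a computational model of what attracts
it, separate the groups. This vignette explains each model in the pipeline,
the tunable parameters and their defaults, what the synthetic cohort does and
does not emulate, and the numerical choices that a maintainer would want
spelled out.

## The display model

All spatial quantities are defined on a 20-inch 4:3 display (40.64 x
30.48 cm, 1600 x 1200 px) viewed from 80 cm, which subtends 28.5 x 21.6
degrees of visual angle at about 56 px/degree (`screen_geometry()`,
`visual_angle()`). Degrees are converted with the horizontal px/degree
figure only; the anisotropy between axes on this geometry is below 1% and
is ignored. Analyses in this package run on any pixel grid with the same
physical geometry: the test suite and the acceptance script use a 160 x 120
rendering (5.6 px/degree) and the analysis scripts 320 x 240, which keeps
Gaussian kernels, disc radii and entropy bounds in the same angular units
while making dense map operations cheap.

## Gaze-density maps, entropy, similarity

Cleaned cyclopean gaze samples are binned into a pixel histogram and
smoothed with an isotropic fovea-sized Gaussian, sigma 55 px on the
1600-px reference grid, about 1 degree (`density_map()`). The figure "55
pixels" is read as the Gaussian sigma rather than a kernel width — it then
matches the ~1-degree fovea on this display — and the kernel is truncated at
3 sigma with border renormalization, so maps sum to exactly 1. Dispersion
of exploration is the Shannon entropy of the map in bits, computed at full
map resolution with `0 log 0 := 0`; similarity between two maps is the
Pearson correlation of the flattened values, and a participant's "similarity
to controls" is the mean over all their pairwise map correlations with
control participants (within-control pairs for controls themselves). The
pairwise reading, rather than one aggregate control map, follows the
all-possible-pairs construction of the control-group reference.

Sample-level cleaning removes samples outside `[0, W) x [0, H)` (0-based
pixels, origin top-left) and a trial is excluded when more than 10% of its
expected samples (nominal duration x nominal rate, 3 s x 60 Hz) are
missing; "more than 10%" is a strict inequality, so a trial missing exactly
10% is retained. Binocular samples are averaged into a cyclopean point;
using a single eye instead is a documented option (`cyclopean_merge(eye=)`),
since the upstream convention is not fixed by the recording model.

## The attention model

For each scene a stack of 22 feature maps is built (`build_feature_stack()`):

* an image-center Gaussian (sigma 1 degree, peak 1);
* a binary background map (1 where no object mask lies);
* three Itti-Koch conspicuity maps (color, intensity, orientation), using
  the classic 1998 architecture: opponent color channels, dyadic Gaussian
  pyramids, center-surround differences at center scales {2,3,4} with
  surrounds c+3 and c+4, zero-DC Gabor energy at 0/45/90/135 degrees, the
  max-based normalization operator N(.), across-scale addition, and min-max
  scaling of each conspicuity map to [0,1]. On small images the pyramid
  depth and scale pairs are reduced (and logged); constant images produce
  exactly zero maps.
* seventeen object-attribute maps: a Gaussian (sigma 2 degrees) at each
  object centroid weighted by the attribute value — the four mask-derived
  properties (complexity, convexity, solidity, eccentricity), the twelve
  binary semantic attributes (face, emotion, touched, gazed, motion, sound,
  smell, taste, touch, text, watchability, operability), plus an
  `object_presence` channel with weight 1 per object. The 4 + 12 = 16
  annotated attributes leave the composition of a 17th object channel
  open; an object-baseline (presence) channel is the natural completion in
  the lineage of object-annotated saliency datasets and is named explicitly
  in the configuration.

Looked locations are sampled uniformly from the pixels in the top 10% of a
trial's density-map values and not-looked locations from the bottom 30%
(ties included before sampling; near-constant maps are skipped with a
warning). Feature values at the sampled pixels are standardized to mean 0,
sd 1 — constant features are dropped and reported with zero weight — and a
linear soft-margin SVM (hinge loss, C = 1, the default of the reference
implementation) is fitted; its primal coefficients are the per-feature
attention weights. `n_per_class = 10` samples per class per trial is the
package default (the upstream choice is not recorded); the validation
experiments use 20. Type-level contributions average the signed
coefficients within each type (center and background are singletons,
low-level has 3 members, high-level 17); sum and mean-of-absolute
aggregations are available behind a flag. Note one structural consequence
of the signed mean: a signal spread over the 17 collinear high-level maps
is divided by 17, while the singleton center map is not, so between-type
magnitude comparisons inherit this scaling. Confidence intervals for group
contributions come from a scene-level bootstrap (resample scenes, re-sample
locations, refit; percentile interval; B = 200 by default), the natural
resampling unit when the model pools samples across scenes.

Group-level fits pool samples across a group's participants and trials;
participant-level fits pool that participant's trials (minimum 10 usable
trials by default, lowered explicitly in small validation cohorts).
Sub-seeds are derived per (unit, participant, scene) so results are
invariant to participant ordering.

## ROI gaze features and the 65-feature vector

Fifteen scene ROIs are built from the annotations: one union mask per
semantic attribute (these may overlap), semantic objects (any flag), other
objects (no flags) and background; the last three partition the image
exactly. Gaze proportion is the fraction of valid raw samples inside a
mask — consistent with the minimal-preprocessing stance, no fixation parser
is used — and a visit is a maximal run of consecutive samples inside a mask,
broken by gaps in the sample clock (e.g. blinks), with duration = run
length / rate. The participant feature vector is 4 type weights + mean
entropy + 15 x 2 proportion mean/sd + 15 x 2 duration mean/sd = 65 values;
standard deviations use n-1 across scenes (the only reading that yields 65
features). Never-visited ROIs contribute zero proportion but are excluded
from duration means — a zero-duration visit is meaningless — and ROIs
visited in fewer than two scenes are imputed as 0 so vectors stay NaN-free.

## Classification

Diagnosis is classified from the 65 features with a linear SVM inside
stratified k-fold cross-validation repeated with fresh fold assignments;
standardization and LASSO-penalized logistic feature selection (penalty by
internal cross-validation) are fitted on each training partition only.
Test scores are pooled within a repeat into one AUC (rank-based; ties count
1/2), three-class problems use one-vs-one vote-margin class scores and the
Hand-Till multiclass AUC, and the CI is the percentile interval of the
per-repeat AUCs. The reference protocol is 20 folds x 20 repeats with 100
label permutations; the validation suite runs 5 x 5 with 49 permutations,
which preserves every structural property being checked (leakage-freedom,
chance behaviour under the null, significance calibration) at desk-scale
cost. Permutation p-values use add-one smoothing, `p = (1 + #{null >=
observed}) / (n_perm + 1)`, so they are never zero. When the chosen LASSO
penalty keeps no features, the first feature entering the path is used
(minimal non-empty set); a fully zero path falls back to all features with
a warning. The clinical baseline applies the same machinery to
antipsychotic use, MMSE, age, sex and education only.

## Group statistics

Measurements indexed by participant and scene are tested with the image as
a blocking factor: `value ~ scene + group`, group F-tested against the
residual. This fixed scene-intercept formulation is equivalent to the
random-image formulation under the balanced designs produced here and keeps
the arithmetic transparent; a true random-intercept fit can be swapped in
where unbalanced data demand it. Post-hoc pairwise comparisons refit the
blocked model per pair with Bonferroni correction, and Hedges' g (with the
small-sample J correction) is computed on participant means. The
median-split object-count analysis and the pupil fatigue check use the
classical two-way mixed design (`group x stratum + Error(participant)`),
with session halves defined by stimulus index. Covariate-adjusted Spearman
correlations rank x, y and the covariates before residualizing — ranking
the covariates too is what removes a shared monotone confound completely;
residualizing ranks on raw covariates provably leaves a nonlinear monotone
remainder in both variables and can fabricate correlation. Stepwise
regression on brain ROIs is forward selection under BIC with age, sex and
education always retained. The a-priori power analysis uses the noncentral
F distribution (`lambda = f^2 N`); f = 0.5, alpha = 0.05, power 0.8 with
three groups gives 14 per group. Stage-wise analyses (MCI vs dementia
subgroups) need no separate machinery: every operation takes the grouping
column as an argument, so filtering rows or relabelling the group column
runs the identical pipeline on a stage subset.

## The synthetic cohort

No gaze recordings ship with the package; every analysis runs on a
generative model whose structure mirrors the attention-model decomposition.

**Scenes.** Procedural multi-object images: non-overlapping ellipses,
irregular polygons and stars (radius 9-18% of the short image side — the
scale of "dominant objects" in annotated scene sets) on a textured
background; object counts drawn Poisson(7), whose median is 7, matching the
median object count of the emulated stimulus set. Semantic flags are
Bernoulli draws at configurable prevalences; the four property values are
measured from the rasterized mask itself. Object properties use standard
region morphology (the upstream set does not define the formulas):
solidity = area / convex-hull area, convexity = hull perimeter / perimeter,
complexity = perimeter^2 / 4 pi area, eccentricity from second-order
moments. Perimeters use the Vossepoel-Smeulders corner-corrected chain
estimator; the raw pixel-chain length would bias complexity upward ~27% on
a disc, and a moving-average-smoothed contour biases it downward at small
radii, while the corrected estimator keeps the disc identities within ~2%.

**Gaze.** Each fixation target is drawn from a three-component mixture:
image center (truncated Gaussian, sigma 1 degree); an object (selected
proportional to baseline + affinity x attributes), targeted at its centroid
with 2-degree Gaussian jitter truncated to the object's own mask; or a
uniform point over the non-object region. Two deliberate design choices
make the attractors semantically disjoint. Truncating object fixations to
the object mask encodes that an object-seeking fixation lands on the
object: with free 2-degree jitter around centroids of objects only a few
degrees across, most "object" fixations would fall on adjacent background,
the gaze-density annulus would make the background map *positively*
predictive of looking under object-driven viewing, and the dominant
attractor would be unrecoverable by construction. Likewise the background
component draws from the region without objects rather than the whole
image, so a "background-biased viewer" is actually that. With both
choices, the generator's contract — recoverability of the dominant
attractor from the fitted attention weights — is well-posed. Fixation dwell times are log-normal (mean 250 ms, sd 100 ms)
divided by the `exploration` parameter, so exploration directly scales the
number of distinct fixations; samples add per-sample jitter (0.15 degree),
blinks arrive as Poisson events invalidating 100-300 ms runs, the pupil
series is baseline + linear drift + noise, and both-eye coordinates are
the cyclopean point +/- 0.2 degree horizontal disparity with jointly
dropped validity.

**Group presets.** CU-like: w = (0.15 center, 0.75 object, 0.10
background), exploration 1.5; AD-like: (0.25, 0.65, 0.10), exploration
1.0; LBD-like: (0.40, 0.50, 0.10), exploration 0.6, with slightly reduced
pupil baseline. These are illustrative parameter choices that reproduce the
qualitative clinical ordering (decreasing exploration and object-driven
attention, increasing center bias from CU to LBD); they are not estimates
of patient behaviour — the source material provides no generative account
of patient gaze — and everything is overridable. Clinical covariates
(MMSE, CDR-SB, gait speed, antipsychotic use, stage, ten z-scored brain-ROI
measures) are drawn from group-conditioned normal/Bernoulli distributions
with plausible desk values chosen once and documented in
`sample_metadata()`.

**What passing tests show.** The synthetic cohort has isotropic fixation
jitter, stationary attractor weights, no saccade kinematics, no calibration
drift and no oculomotor pathology; passing the validation suite therefore
demonstrates that the *pipeline* measures what it claims on data with known
structure (recovering planted attractors, orderings and effect sizes), not
that real AD/LBD gaze obeys this generative model. The real-cohort headline
statistics (group AUCs 0.76/0.87/0.82, the reported Hedges' g and
correlation values) depend on the unavailable patient recordings and are
out of reach by construction.

## Validation scales and numerical choices

The validation experiments use fixed problem sizes chosen for stable Monte
Carlo behaviour: attention recovery runs 3 dominant-attractor scenarios
(center 0.9/0.05/0.05; object 0/0.95/0.05; background 0/0.05/0.95, all at
exploration 2, chosen a priori so each scenario's dominant component is
unambiguous) x 40 replicates on 20 shared scenes with 5 viewers each;
entropy monotonicity uses a 5-point exploration grid x 6 seeds x 8 scenes;
classification checks use 5 x 5 CV on feature-level cohorts (20/group
separable, 80/group null — the null size keeps the chance-AUC standard
error near 0.035); ANOVA calibration uses 1000 null replicates of 18
participants x 4 scenes (enough that the Monte-Carlo error of the
type-I-error estimate is well below the 2-point tolerance around the
nominal 5%). Zero center weight in the non-center recovery
scenarios is deliberate: the center is a single narrow landmark, and even a
small admixture of center fixations leaves a center signature that is not
part of the attractor under test.

Other numerical conventions: percentile ties at the 10%/30% sampling
thresholds include the whole tied set before sampling; degenerate
(near-constant) maps skip the scene with a warning rather than fabricating
samples; SVM weight vectors are re-oriented so positive scores always mean
"looked"; all stochastic steps derive sub-seeds from a single base seed via
a deterministic string hash, so results are reproducible and invariant to
iteration order; and the `>10%` QC rule, the 2-degree center disc radius
and the 55-px kernel sigma are all exposed as arguments.

## Known limitations

Itti-Koch conspicuity is computed with the 1998 max-normalization; the
iterative DoG refinement is not implemented. The attention model's type
contributions inherit the signed-mean scaling noted above, so absolute
magnitudes are comparable within a type across groups, not across types.
The mixed ANOVA's fixed-blocks formulation understates image-level variance
under severe imbalance. The synthetic generator does not model saccade
trajectories, smooth pursuit, or the oculomotor abnormalities of
parkinsonian disease, and its clinical covariates are independent of the
gaze process given the group label, so severity correlations in synthetic
data are null by construction.
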