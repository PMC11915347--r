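---
title: "Methods: microstructural-functional connectivity co-development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstructural-functional connectivity co-development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions, and the
limits of what its synthetic validation can show.

## The atlas and edge conventions

All matrices live on a fixed 75-region grey-matter atlas: the 31 DKT
cortical labels per hemisphere (62 cortical ROIs, six lobes: frontal,
parietal, temporal, occipital, cingulate, insular) plus 13 subcortical
parcels (medial brainstem and bilateral thalamus, caudate, lenticular
nucleus, amygdala, hippocampus, cerebellum). The cortical label roster is
the standard 31-label DKT cortical scheme; the cerebellum is treated as
subcortical because it is delineated with the subcortical volumetric
parcels. Homotopy links the left and right instance of the same label; the
brainstem, being medial, has none.

Edges are vectorized in one fixed convention: the row-major upper triangle
with `i < j`, 1-based (R's native indexing; `edge_pairs()` makes the order
explicit), giving 2775 edges. The five edge categories
(cortico-subcortical, subcortico-subcortical, intra-hemispheric
cortico-cortical, inter-hemispheric homotopic, inter-hemispheric
non-homotopic) are exhaustive and mutually exclusive; subcortico-subcortical
edges — which the named analysis subsets do not cover — are retained in
whole-brain analyses and excluded from the stratified ones so that the
categories partition all 2775 edges. Primary sensorimotor (precentral,
postcentral, paracentral) and visual (pericalcarine, lateral occipital,
cuneus) tags, and the thalamo-cortical flag, drive the system subsets.

## Microstructural connectivity

MC treats each ROI's multi-metric diffusion profile across the subjects of a
group as a fingerprint and correlates fingerprints between ROIs. Three
preparatory steps precede the correlation, each per group:

1. **Confound residualization.** For every (ROI, metric) column, OLS
   residuals on `[1, PMA, GA, g_m]`, where `g_m` is the subject's global
   median of metric *m* over all 75 ROIs, itself residualized on
   `[1, PMA, GA]`. All regressors enter jointly in a single projection —
   a sequential scheme would make the result depend on regressor order.
   The global covariate is computed per metric (a pooled global measure
   would mix units). At least 5 subjects are required (4 regressors with
   intercept); rank-deficient designs error, naming the collinear columns.
2. **Min–max scaling** to [0, 1], pooling values across all regions and
   subjects within the group, *per metric*: diffusivities (mm²/s, ~10⁻³)
   and unitless indices are incommensurable, and pooling across metrics
   would let whichever metric has the widest spread dominate every
   fingerprint. The choice is exposed for sensitivity analysis simply by
   rescaling inputs; Pearson correlations are invariant to any affine map
   applied uniformly to a metric, so scaling matters only through the
   per-group pooling.
3. **Fingerprint concatenation**, subject-major (subject 1's six metrics,
   then subject 2's, ...). Any fixed order gives the same correlation as
   long as ROI vectors stay aligned; the test suite asserts exact
   invariance under a common subject permutation.

MC is signed; downstream group analyses use `absolute_mc()` because the
magnitude of covariance, not its sign, is the quantity of interest there.
The diagonal is forced to exactly 1 after the correlation to guard against
floating-point drift.

## Functional connectivity

Per subject: zero-phase (forward–backward) 4th-order Butterworth low-pass at
0.1 Hz — zero-phase so that filtering cannot introduce lag-driven
decorrelation between regions; then per-ROI z-scoring using the mean and SD
of the retained (post-trim) support, so retained series have mean 0 and
SD 1 exactly; then trimming of the first and last 50 samples (filter
transients). The default sampling interval is 0.392 s, matching
high-temporal-resolution neonatal EPI. A retained length below 50 samples
is an error — Pearson correlations are too unstable below that. Group FC is
the plain elementwise mean of subject matrices; a Fisher-z averaging variant
exists behind a flag (default off) since plain averaging of correlation
matrices is the convention this pipeline follows. Image-space smoothing
belongs to upstream preprocessing and is out of scope here.

## Longitudinal change

`ΔMC = |MC₂| − |MC₁|` needs no further adjustment because the metrics
feeding MC were already age-corrected within each group. For ΔFC the
session difference of group means is weighted by
`1 − overlap(CI₁, CI₂)` per edge. Two decisions were genuinely open:

* **CI form.** The implemented default is the 95% confidence interval of
  the group mean: half-width `1.96·SD/√n`, built from the across-subject SD
  of the connection. A mean-CI shrinks with n, so reliable differences
  survive while noisy ones are damped; `z_mult` and an SD-without-√n option
  are configuration parameters.
* **Overlap measure.** Jaccard (intersection length / union length):
  bounded in [0, 1], symmetric, 1 for identical intervals, 0 for disjoint
  ones. Two degenerate equal intervals count as fully overlapping.
  An intersection-over-shorter-interval alternative is selectable.

ΔFC is exactly antisymmetric under session swap, and `|ΔFC|` never exceeds
the raw mean difference — both are asserted in the tests.

## Edge statistics

The Huber robust regression is implemented in-package as iteratively
reweighted least squares: tuning constant 1.345 (95% Gaussian efficiency),
residual scale re-estimated each iteration by the MAD, convergence when the
coefficient change falls below 1e-8, at most 100 iterations (non-convergence
is an error), asymptotic sandwich SE for the slope. An independent
implementation (`MASS::rlm`) serves as a cross-check in the test suite.
Permutation p-values for slopes shuffle the response against the predictor
and use the add-one estimator `(1 + k)/(1 + N)` — never exactly zero, and
converging to the plain proportion of more-extreme shuffles as N grows.
Shuffling one margin is distributionally equivalent to shuffling both. The
predictor/response assignment is explicit in the API (MC predicts FC in
MC-FC fits); Huber slopes are not symmetric under exchange, which is also
why the co-evolution hypothesis family runs the ΔFC~ΔMC regression in both
directions (six regressions in total: the co-evolution pair, ΔFC against
session-1 MC, session-2 FC against ΔMC, ΔMC against session-1 FC, and
session-2 MC against ΔFC).

The paired Wilcoxon test drops zero differences and reports the
smaller-rank-sum statistic `W = min(T⁺, T⁻)` — stated explicitly because
printed W values depend on this convention. Top-fraction thresholding
defines the threshold as the `ceil(fraction · n_edges)`-th largest value
(of one matrix in adapted mode, of the pooled values in common mode) and
keeps ties at the threshold (`≥`), which is deterministic and
order-independent; with all-distinct values exactly
`ceil(fraction · n_edges)` edges survive.

## Networks and mutual information

Connectivity is converted to the cosine-theorem distance
`d = √(2(1 − r))`, which is the Euclidean distance between standardized
profiles correlating at `r`. MC uses `|r|`; FC keeps the signed `r`
(anticorrelated regions are functionally distant); both choices are flags.
ΔMC/ΔFC values are clipped to [−1, 1] before conversion (ΔFC can in
principle exceed the unit interval; in practice it does not). Ward
clustering runs on this distance via the Lance–Williams update on squared
distances (`hclust(method = "ward.D2")`), which is exactly Ward's variance
criterion for Euclidean input and is deterministic for a given matrix.

Dendrogram overlap is the raw mutual information (natural log) between cuts,
computed for **every** cluster-size pair `(k_a, k_b)`, k from 2 to 75 — no
"optimal k" is selected, deliberately. Raw rather than adjusted MI is used
because each cell carries its own permutation null, which plays the role a
chance adjustment otherwise would: one labeling is shuffled 100 times
(cluster sizes preserved), and a cell is significant when the observed MI
exceeds the null's 95th percentile, computed by the nearest-rank method —
unambiguous on a 100-value sample. Significant cells are summarized by mean
and SD; an empty significance mask yields a defined "no significant
overlap" result (`NA` mean, count 0), not an error.

Two implementation notes. First, the null computation is batched: all 100
shuffles of a pair are evaluated through one sorted code vector using
`MI = H(a) + H(b) − H(a,b)` (H(b) is shuffle-invariant because shuffling
preserves cluster sizes); the tests verify bit-level agreement with the
direct contingency-table route. Second, within one dendrogram comparison the
same 100 shuffle draws (seeded from the comparison's seed) are applied to
every cluster-size pair; each cell still receives its own 100-value null of
its own cuts, and `mi_permutation_null()` draws fresh shuffles on every
call.

## The synthetic cohort generator

The generator is the package's study-condition definition, not a tuning
knob. It emulates: three groups of 45 subjects (preterm pairs keep identity
— same ids and GA — across sessions); PMA at scan uniform on 28.3–36.9
weeks (session 1) and 38.4–44.9 weeks (session 2 and term controls), drawn
independently between sessions and always at least 0.1 weeks after GA at
birth (uniform 25.6–36.0 weeks preterm, 37.4–42.3 weeks term); regional
metrics from a latent-factor block model

```
x = mu_m(block(r)) + beta_PMA,m (PMA − 40) + beta_GA,m (GA − 35)
    + g_s + lambda_b f_{s,b} + epsilon
```

with one standard-normal factor per block per subject — a latent-factor
construction guarantees a positive semi-definite covariance and direct
control of the within/between-block contrast, which explicit covariance
matrices would not; and ROI time series
`√ρ_b · latent_block + √(1 − ρ_b) · noise`, white Gaussian. Defaults:
block loading 0.8, within-block time-series correlation 0.6, noise SD 0.1,
global offset SD 0.1, per-(block, metric) mean offsets with SD 0.2,
confound slopes 0.02 (PMA) and 0.01 (GA) latent units/week, T = 300 samples
at 0.392 s. Latent values are mapped affinely onto plausible physical
scales per metric (FA ≈ 0.30 ± 0.04, diffusivities ≈ 1.2×10⁻³ mm²/s,
NDI/ODI ≈ 0.3–0.4); every downstream statistic is Pearson-based and
therefore invariant to that map. Longitudinal change is planted through
per-block session-2 parameters (`mc_loading_ses2`, `fc_rho_ses2`), which
also yields the coupled-versus-independent cohorts used to probe the
directionality hypotheses: in the coupled condition the same blocks
strengthen in both modalities between sessions; in the independent
condition disjoint blocks change.

One RNG stream per cohort is split into named substreams (covariates,
metrics, timeseries), so adding draws to one component never perturbs
another; the whole cohort is bit-reproducible from `(config, seed)`.

**What the generator does not emulate:** hemodynamics, motion and scanner
artifacts, spatially varying parcellation error, non-linear age effects,
heavy-tailed metric noise, and any geometric structure (no image space at
all). Passing recovery tests therefore shows the *statistical machinery* is
correct and calibrated — orthogonalization removes linear confounds, Ward
plus MI recovers planted partitions, permutation nulls are uniform — not
that the pipeline is robust to real-data artifacts upstream of the ROI
tables.

## Validation conditions and problem sizes

The recovery and calibration experiments run at the emulated study scale
where it matters and scale down where only calibration is probed: 45
subjects per group and 5 planted blocks for confound-removal and network
recovery; 500 repeats of 100-shuffle nulls over 75 ROIs for MI calibration;
200 repeats at 200 permutations on 2775-edge null vectors for slope-p
uniformity; ten seed pairs of coupled/independent cohorts for the
co-evolution discrimination; and a 12-subject, reduced-permutation
configuration for the byte-identical determinism check of the orchestrated
pipeline. These sizes are the package's validation design; all of them are
recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Group-wise MC has no subject-level analogue here (deliberately: six
  metrics per ROI are too few for stable subject-level covariance), so MC
  uncertainty cannot be propagated into ΔMC the way FC spread feeds ΔFC.
* The CI-overlap weight and its multiplier are conventions; results near
  the significance boundary can shift under the alternative overlap
  measure, which is why both are logged configuration options.
* MI between dendrogram cuts compares partitions, not geometry: two
  clusterings can overlap strongly while differing in which specific
  regions swap at fine scales.
* With only 100 shuffles the smallest achievable null-exceedance level per
  cell is coarse; the 95th-percentile rule is a screening criterion, not a
  calibrated per-cell p-value.
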