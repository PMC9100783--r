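---
title: "Classifying mental-health symptoms from task EEG source features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mental-health symptoms from task EEG source features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosym)
```

## The problem and the model

Each subject in a cognitive-EEG cohort contributes a complete tensor of
baseline-corrected, source-localized spectral amplitudes over 68
Desikan–Killiany cortical regions, three frequency bands (theta, alpha,
beta) and five cognitive tasks — 1020 signed values per subject — plus four
integer self-report scores (GAD-7 anxiety, PHQ-9 depression, ADHD-RS
inattention and hyperactivity). A subject is labeled symptomatic for an
instrument when the score is at least 5.

The pipeline predicts each binary label with L2-regularized logistic
regression,

$$\min_w \sum_i \log\!\bigl(1 + e^{-y_i w^\top x_i}\bigr) + \lambda\, w^\top w,
\qquad y_i \in \{-1, +1\},\ \lambda = 1,$$

not on the raw tensor but on an augmented feature universe built in three
deterministic stages:

1. **Statistical summaries.** Seven measures (max, min, range, mean, std,
   0.75- and 0.25-quantile) are computed over the ROI axis for each
   (band, task), over tasks for each (ROI, band), and over bands for each
   (ROI, task). At full scale this takes 1020 identity features to
   $1020 + 105 + 1428 + 2380 = 4933$.
2. **Pairwise products.** Every unordered product of two stage-1 features
   is a candidate interaction feature: $4933 + \binom{4933}{2} =
   12{,}169{,}711$ features.
3. **Calibrated log twins.** Every feature also gets
   $\log(1 + (x - \min x)/(\max x - \min x)) \in [0, \log 2]$, doubling the
   universe to $24{,}339{,}422$.

The universe is never materialized. It is streamed in a fixed order
(stage-1 singletons, then pairs in lexicographic order, each base feature
immediately followed by its log twin) and scored with the continuous
chi-square statistic
$\chi^2(D, c) = \sum_{c \in \{0,1\}} (S_c - E_c)^2 / E_c$, where $S_c$ is
the sum of feature values in class $c$ and $E_c$ the expected sum under the
class proportions. The top $k$ features (default $k = 40{,}000$) feed the
classifier; training folds are additionally balanced by SMOTE and expanded
nine-fold with Gaussian noise whose per-feature variance is 1/100 of the
observed variance.

Interpretation comes from aggregation rather than coefficients: every
product feature whose two constituents carry concrete, distinct ROIs adds
its chi-square mass to that ROI pair's *strength*. The strength matrix
defines a weighted graph over the 68 regions (edges where strength exceeds
a threshold, 100 by default), on which current-flow closeness and
betweenness centralities — the resistor-network generalizations of the
shortest-path centralities — identify "hub" regions per symptom. Per-pair
sub-accumulators over bands, tasks and the log flag answer which factor
dominates each connection.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| labeling threshold | 5 | score-to-label cut (score ≥ 5 → symptomatic) |
| `k` | 40,000 | features kept by chi-square selection |
| `lambda` | 1 | L2 penalty weight, unitless |
| folds × repeats | 5 × 5 | stratified CV geometry (25 fold evaluations) |
| SMOTE `k_neighbors` | 5 | minority neighbourhood for interpolation |
| Gaussian factor / scale | 9 / 0.01 | noisy copies appended; noise variance fraction |
| strength threshold | 100 | hub-graph edge cut on pair strength |
| `n_perm` | 100 | label permutations for the null accuracy distribution |

## Design choices where the method is underdetermined

**Chi-square calibration.** The statistic is defined for non-negative
values, but baseline-corrected amplitudes and especially their pairwise
products are signed. Features are therefore min-max calibrated to
$[0, 1]$ before scoring. Because the statistic is *linear in the scale of
the feature* ($\chi^2(a x) = a\,\chi^2(x)$), calibrating only the signed
features while passing non-negative ones (range, std, and their products,
which live on a ~10× larger scale) through untouched makes the ranking
reward scale rather than association; in simulation this buries genuinely
predictive features under large-scale noise. The default is therefore to
calibrate **every** feature (`calibrate = "always"`), making the ranking
invariant to per-feature affine scale; `calibrate = "negative_only"` is
available for the uncalibrated pass-through behaviour. The exported
`nonneg_calibrate()` primitive retains the pass-through default so that
already non-negative inputs are untouched when scored directly.

Note also what min-max calibration implies: the statistic compares class
*sums*, so a single extreme value stretches the range and compresses the
bulk of the distribution, weakening the score of heavy-tailed features
(products of two near-Gaussian cells are heavy-tailed by construction).
Detection of region-pair interactions in practice rests on the *aggregate*
strength of the many correlated cell products of a region pair, not on any
single product — which matches the hub-graph reading of the results.

**Leakage control.** The published description selects features on the
whole cohort before cross-validation. The default here
(`leakage = "fold_safe"`) re-runs scoring, selection and all calibrations
inside each training fold, so reported fold accuracies are honest;
`leakage = "paper_faithful"` reproduces whole-cohort selection. Both modes
oversample training folds only.

**Other fixed conventions.** Population standard deviation (divide by
$n$); type-7 (linear-interpolation) quantiles; a constant feature maps to
all zeros under either calibration and contributes zero chi-square; ties
in selection break toward the earlier stream position; the intercept is
included and unpenalized (a switch disables it); features are standardized
with training-fold means and sds before fitting, since L2 penalties are
scale-sensitive. SMOTE balances first, then Gaussian replication expands
the balanced set (order configurable). In the permutation null the fold
partition is computed once from the observed labels and held fixed across
permutations — class counts are preserved, folds stay stratified in
expectation, and the expensive product/log pass over the universe is then
shared by all permutations. Test-fold values that fall outside a training
fold's log-calibration range are clipped into it so the transform stays
defined.

**Hub-graph conventions.** Edges are keyed on pair strength (the
vertex-strength-sum reading is available as `mode = "vertex_sum"`).
Products of two features within one ROI are excluded from edges and vertex
strengths and counted as skipped. Constituents with an aggregated band or
task still contribute to pair strength, but only concrete levels compete
for dominance. Current-flow closeness of vertex $i$ in a component of size
$n_c$ is $(n_c - 1) / \sum_j r_{ij}$ with $r$ the effective resistance
(edge weights as conductances); current-flow betweenness averages each
interior vertex's current throughput over all $\binom{n_c-1}{2}$
source–sink pairs involving other vertices, normalized by
$(n_c-1)(n_c-2)/2$, hence lies in $[0, 1]$. Both are computed per
connected component from the Laplacian pseudo-inverse; singleton
components are reported as undefined rather than zero.

## What the synthetic generator emulates

`generate_cohort()` draws, per subject, a zero-mean Gaussian tensor with
equicorrelation 0.6 among the 15 band × task cells of each ROI — band- and
task-wise amplitudes of a single cortical source share most of their
variance in real recordings, and this within-region coherence is exactly
what makes region-level aggregation meaningful. Symptom scores arise from
a latent logistic score: planted main effects add
$\beta \cdot z_{\text{cell}}$ and planted interactions add
$\beta \cdot z_{\text{cell}_1} z_{\text{cell}_2}$ (distinct ROIs) in
log-odds units, plus a shared per-subject factor (loading 0.6) that
induces a modest positive correlation between the four instruments'
scores, plus standard logistic noise. The latent is mapped to integer
scores by rank binning: the top fraction matching the target prevalence is
spread monotonically over $[5, \text{ceiling}]$, the rest over $[0, 4]$ —
prevalence control without distributional assumptions. Instrument ceilings
are 21 (GAD-7) and 27 (PHQ-9, ADHD-RS subscales). Default prevalence is
0.35 per symptom, a plausible rate for mild self-reported symptoms in
healthy adults; the source cohort's split is unpublished, so this is
configurable.

What the generator does **not** emulate: EEG time series, volume
conduction, source-localization error, task-specific topographies,
non-Gaussian amplitude distributions, missing data, or realistic
inter-region (as opposed to within-region) correlation structure.
Passing recovery tests on these cohorts shows the pipeline's machinery is
correct and has power under its own assumptions — not that the published
real-cohort accuracies are reproducible; those require the private
97-subject dataset.

## Problem sizes used in the shipped tests

Recovery studies run at a reduced scale chosen to exercise every stage in
reasonable time: cohorts of $n = 200$ subjects, 16 ROIs (a 240-cell
tensor; 1241 stage-1 features; about 1.5 million universe features), one
planted cross-ROI interaction at $\beta = 5$ with balanced labels,
$k = 300$ selected features (the accuracy plateau at this scale, mirroring
the plateau logic used to pick 40,000 at full scale), 5-fold
cross-validation with one repeat per cohort seed, ten cohort seeds, and a
100-permutation null of the full pipeline on a matched null cohort. The
effect size sits in the regime where single-feature detection is marginal
but region-pair aggregation is reliable, which is the interesting regime
for this method. Oracle tests (brute-force universe scoring, electrical
network solves) run on toys small enough to materialize exhaustively.

## Known limitations

* The continuous chi-square ranking remains sensitive to distribution
  shape even after calibration; heavy-tailed features are systematically
  under-ranked relative to an equally associated well-spread feature.
* At the full 24.3M-feature scale a fold-safe evaluation re-scores the
  universe per fold; this is embarrassingly parallel but serial runtime is
  dominated by the `log` evaluations of the twin features.
* The atlas ID convention (alphabetical Desikan–Killiany regions,
  left = odd, right = even) is a reconstruction consistent with all
  published id/name pairs, not an independently published table; supply
  your own atlas mapping if your parcellation differs.
* Strength aggregation covers every product feature with two concrete,
  distinct ROIs — 2 × (71 choose 2)-per-pair-block features at full scale;
  the aggregate's absolute scale therefore depends on cohort size and
  calibration mode, and only relative comparisons (rankings, dominance)
  are meaningful.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulate = synthetic_config(
    n_subjects = 200, n_roi = 16, prevalence = 0.5, seed = 42,
    effects = planted_effect("anxiety", "interaction",
                             list(c(3, "alpha", 2), c(9, "alpha", 2)),
                             beta = 5)),
  symptoms = "anxiety", variants = c("original", "da_fs_os"),
  k = 300, folds = 5, repeats = 1, n_perm = 0, strength_threshold = 100,
  seed = 1)
res <- run_pipeline(cfg, "anxiety_run")
summary(res$results$anxiety$da_fs_os)
print(res$results$anxiety$graph)
head(res$results$anxiety$centralities)
```
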