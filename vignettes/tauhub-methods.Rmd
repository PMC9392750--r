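---
title: "Hub-weighted tau-PET analysis: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-weighted tau-PET analysis: models, assumptions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauhub)
```

## The scientific question

In Alzheimer's disease, tau pathology does not spread uniformly: there is
evidence that in patients with younger symptom onset, tau accumulates
preferentially in globally connected cortical *hubs* — regions with short
functional-connectivity-based distance to the rest of the brain — and that
a hub-weighted deposition pattern predicts faster subsequent tau
accumulation and cognitive decline. `tauhub` implements the full analysis
chain needed to test this at the ROI level: hub-map construction from
functional connectivity, mixture-model cleaning of tau-PET SUVRs,
subject-level pattern scoring, longitudinal rate estimation, and the
associated inferential battery.

## The hub map

Subject connectivity is Pearson correlation of ROI timeseries, Fisher-z
transformed (`compute_connectivity()`, correlations clipped at
|r| = 0.999999 so duplicated signals stay finite). Subject matrices are
averaged (`average_connectomes()`), the strongest 30% of edges retained
(`threshold_density()`; ranking is by signed z, so at realistic densities
negative edges are excluded — a retained non-positive weight is an error,
never silently inverted), and the thresholded graph converted to
connectivity-based distance with edge length 1/weight and all-pairs
shortest paths (`distance_matrix()`, Dijkstra via igraph). A ROI's
*weighted degree* is its mean distance to all remaining ROIs
(`weighted_degree()`), and the scaled hub map
(`scale_hub_map()`) is the linear rescale of that vector to [-1, 1] with
the sign flipped: +1 = most hub-like. The same chain applied to one
subject's matrix gives a subject-level hub map.

Numerical choices: ties at the density cutoff are broken by lexicographic
(row, column) index, so thresholding is reproducible across platforms; a
disconnected thresholded graph is a hard error (at 30% density this does
not occur in realistic connectomes, and the synthetic generator
guarantees connectivity); the rescale requires non-constant mean distance.

## Tau positivity

Flortaucipir tau-PET carries off-target binding. For each ROI, baseline
SUVRs across the cohort are modelled as either one Gaussian (pure
off-target) or a two-Gaussian mixture (off-target plus a right-shifted
pathological component); both are fitted by maximum likelihood
(`fit_roi_gmm()`: a model-based hierarchical initialization plus at least
five seeded random EM restarts) and compared by AIC. Tau positivity is the
posterior probability of the pathological component times the SUVR —
an SUVR "cleaned" of the off-target curve.

Two guards matter in practice and are deliberate design choices:

* **Separation floor.** AIC alone endorses a spurious two-component split
  of genuinely unimodal data in roughly a tenth of samples; the two
  overlapping pseudo-components then label the upper half of off-target
  noise as tau-positive. A two-component fit is therefore only accepted
  when its component means are at least 2 pooled SDs apart
  (`min_separation`); genuine off-target/target separation in SUVR data
  sits far above this floor (typically 3+).
* **Left-tail zeroing.** With unequal component variances the wide
  pathological component dominates *both* tails, so a pure Bayes
  posterior would mark implausibly low SUVRs as tau-positive. SUVRs at or
  below the off-target mean are scored 0, which also makes the transform
  monotone in SUVR over its operative range.

Mixtures are fitted on baseline scans only and reused for follow-up
visits, keeping positivity comparable over time. ROIs where the
single-component model wins are scored 0 with a logged message.
Positivities below 1e-12 are floored to 0.

## The tau hub ratio and epicenters

The subject-level statistic is the positivity-weighted mean of the hub
map:

$$\mathrm{tau\ hub\ ratio} =
  \frac{\sum_i \mathrm{positivity}_i \times \mathrm{scaled\ hub}_i}
       {\sum_i \mathrm{positivity}_i}$$

Dividing by total positivity adjusts for global tau burden: the ratio is
invariant to rescaling the positivity vector, bounded in [-1, 1], and
moving deposition mass up the hub gradient can only increase it. A
subject with no suprathreshold tau anywhere has no defined pattern; such
subjects are flagged rather than scored (`subject_hub_metrics()` reports
them and carries `NA` metrics).

Tau *epicenters* are the 10% of ROIs with highest baseline positivity
(count `ceiling(fraction * n_roi)`, boundary ties broken by ROI id);
epicenter hub-ness is the mean connectivity-based distance of that set —
lower = more hub-like.

## Longitudinal rates

Per ROI, tau positivity is modelled as a linear mixed model on years from
baseline with subject-level random intercepts and slopes (lme4). The
per-subject annual rate is the fixed slope plus the subject's predicted
(BLUP) random slope — not a per-subject OLS fit — and the global
accumulation rate is the mean of the ROI rates. Cognition change rates
use the same machinery on the composite score. Singular fits fall back
along a documented chain: if the intercept-slope correlation sits on the
boundary but slope variance is real, the correlation is dropped;
otherwise the model keeps a random intercept only and the ROI is flagged.
ROIs with constant (all-zero) positivity short-circuit to zero rates.
Subjects with a single visit are excluded and reported. Because every ROI
model shares one design (same subjects, same visit times), fitted
structures are reused across ROIs (`lme4::refit`), which keeps a
200-ROI cohort fit in seconds; optimizer tolerances are loosened to 1e-6
on the deviance scale, far below any quantity interpreted downstream.

## Inference

* `standardized_regression()` — OLS on complete cases (listwise deletion,
  counted); betas standardized as b·SD(x)/SD(y); two-sided t-based p
  values. Rank-deficient designs error, naming the collinear columns.
* `exact_permutation_test()` with `shuffled_ratio_null()` — re-runs the
  identical regression on hub ratios built from connectomes whose
  upper-triangle values are randomly permuted; two-sided exact p
  = (1 + #{|β₀| ≥ |β̂|}) / (1 + n_perm). Failing null draws (e.g., a
  shuffle that disconnects) are redrawn with a fresh sub-seed and
  counted. The null generator evaluates the regression through the
  Frisch–Waugh identity on pre-residualized covariates; a test asserts
  equality with the full regression to 1e-10.
* `sliding_window()` — subjects sorted by global tau; a window of 30% of
  the sample shifted in steps of 3 subjects; within each window, mean
  outcome for subjects above vs. below the full-sample median hub ratio
  (the median is computed once on the full sample — a config-level choice;
  per-window medians would leave strata nearly empty in small windows).
  The burden × ratio interaction is tested by OLS with standardized
  coefficients on the full sample; a window with an empty stratum reports
  a missing mean rather than being dropped.
* `bootstrap_mediation()` — x, m, y standardized; path a from
  m ~ x + covariates, path b and the direct effect from
  y ~ x + m + covariates; the indirect effect is a·b with a seeded
  case-resampling percentile bootstrap (default 10,000 draws) and a
  two-sided bootstrap-tail p value. Variables are standardized before
  path estimation so the indirect effect is in standardized units.

Alpha is 0.05 throughout, with no multiple-testing correction, matching
the analysis convention the pipeline implements.

## The synthetic cohort

Real tau-PET cohorts are access-restricted, so validation runs on a
generator whose statistical structure matches the pipeline's assumptions
and whose ground truth is recorded for every recovery test
(`cohort_config()`, `generate_connectome()`, `generate_cohort()`).

* **Connectome**: 200 ROIs, 40 designated hubs; edges touching hubs drawn
  from Normal(0.5, 0.1) vs Normal(0.2, 0.1) elsewhere (Fisher-z scale,
  floored at 0.01); redrawn (counted) if the thresholded graph
  disconnects. A further 40 non-hub ROIs form a "limbic-like" seed set
  that carries early tau burden, imitating the temporo-limbic
  predominance of early deposition.
* **Groups**: CN amyloid-negative (90), preclinical (60), MCI (90),
  dementia (60) — 150 symptomatic subjects; ages and education mirror a
  typical amyloid-stratified cohort.
* **Burden**: each subject has an expected number of tau-affected ROIs
  graded by diagnosis (0.2 / 6 / 28 / 36) with lognormal within-group
  dispersion (SD 0.3 on the log scale) reproducing the wide burden spread
  of real cohorts. A latent hub loading λ ∈ [0, 1] mixes the deposition
  weights from the seed set toward the hub set. In symptomatic subjects λ
  depends on standardized age at the planted standardized effect −0.4; in
  preclinical subjects it is age-independent.
* **SUVRs**: off-target Normal(1.05, 0.05); affected ROIs add a target
  shift Normal(+0.5, 0.2). Three visits over two years; affected ROIs
  accumulate with a subject-level slope; visit noise SD 0.02.
* **Rates**: the subject's true global accumulation rate is centred at
  slope_mean × expected burden fraction, with within-group relative
  spread `rate_cv = 1` whose standardized hub-loading share equals the
  planted +0.4; per-ROI slopes are backed out over the affected set
  (capped at 0.15 SUVR/yr for plausibility). Standardizing λ within
  diagnostic group makes the planted effect a within-stratum coefficient
  that survives diagnosis adjustment, and the group-graded rate scale is
  what makes hub-weighted deposition increasingly consequential at higher
  burden — the sliding-window interaction.
* **Cognition**: baseline composite by group; annual decline
  −0.05 ± 0.08/yr tracking the standardized true global rate at −0.35;
  per-visit noise 0.04. The noise level was chosen so that a 3-visit
  random-slope model can actually identify subject slopes (the
  correlation bound for BLUP slopes is τ/√(τ² + σ²/2); at larger noise no
  estimator could reach the 0.9 recovery the tests demand).

What the generator does *not* emulate: spatial autocorrelation of ROI
signals, non-Gaussian noise, scanner/site effects, off-target structures
with spatial topology (e.g., choroid plexus), dropout or irregular visit
schedules. Passing recovery tests therefore demonstrates the pipeline's
correctness under its own model class, not robustness to those real-data
complications.

## Validation strategy and problem sizes

The test suite validates in layers: graph primitives against brute-force
oracles (Floyd–Warshall, sort-and-take, element loops) on 50 random
connected graphs of up to 25 ROIs; the hub-ratio algebra exactly;
mixture-model selection and recovery on planted distributions; mixed-model
slope recovery in the noiseless limit (exact to 1e-6) and under noise
(per-subject global rates correlate ≥ 0.9 with planted slopes when a
subject's slope is expressed across 10 ROI trajectories — with a single
trajectory the information bound τ/√(τ² + σ²/2) ≈ 0.82 makes 0.9
unreachable at that noise, which is why subject rates are always
aggregates here); exact-test size calibration on a fully null cohort
(500 replicates at 199 permutations on a 24-ROI template, rejection
within [0.03, 0.07]); mediation point recovery and CI coverage (200
replicates); and the end-to-end qualitative result pattern — all six
planted directional effects — on 100 seeded replicates of the full-size
default cohort. Replicate counts and graph sizes are the package's own
choices balancing Monte-Carlo resolution against a test suite that runs
in minutes.

## Known limitations

* The hub metric is the mean shortest-path distance; the field sometimes
  labels this "weighted degree", and the package keeps that label, but it
  is not the formal graph-theoretic weighted degree (sum of edge
  weights). Alternative hub metrics (betweenness, participation
  coefficient) are out of scope.
* Group hub maps are computed once from the averaged thresholded matrix,
  not averaged over per-subject hub maps.
* The 1000 shuffled-connectome null models reshuffle the group matrix
  (one hub map per null iteration); per-subject reshuffling is not
  implemented.
* Whether follow-up visits should contribute to mixture fitting is
  undecidable from first principles; fitting on baseline only keeps
  positivity longitudinally comparable and is the package's contract.
* Near-zero-positivity subjects (amyloid-negative controls) have an
  ill-defined deposition pattern; the package flags them rather than
  imputing a ratio.
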