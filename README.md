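# tauhub

Hub-weighted analysis of tau-PET deposition patterns in Alzheimer's
disease, for researchers working with ROI-level tau-PET and functional
connectivity data.

In AD, tau pathology in *globally connected brain hubs* — cortical
regions with short functional-connectivity-based distance to the rest of
the brain — is a candidate driver of aggressive, early-onset disease.
`tauhub` quantifies, per subject, how hub-weighted a tau deposition
pattern is, and provides the statistical machinery to relate that
pattern to age, tau accumulation rates, and cognitive decline.

## The method

1. **Scaled hub map.** ROI timeseries are cross-correlated and Fisher-z
   transformed; subject matrices are averaged, density-thresholded at
   30%, and converted to connectivity-based distance (edge length
   1/weight, all-pairs shortest paths). Each ROI's mean distance to the
   remaining ROIs is rescaled to [−1, 1] with +1 = strongest hub.
2. **Tau positivity.** Per ROI, a two-component Gaussian mixture
   separates off-target from pathological tau-PET binding (AIC model
   selection against a single Gaussian, with a component-separation
   guard); positivity = P(pathological | SUVR) × SUVR.
3. **Tau hub ratio.** The subject-level statistic

   ```
   tau hub ratio = Σ_i (positivity_i × scaled_hub_i) / Σ_i positivity_i
   ```

   is the positivity-weighted mean of the hub map: positive =
   hub-weighted deposition, negative = non-hub-weighted, invariant to
   overall tau burden. Tau *epicenters* (top 10% positivity ROIs) and
   their mean connectivity-based distance give a complementary
   epicenter hub-ness measure.
4. **Rates.** Per-ROI linear mixed models (random intercept + slope)
   give each subject a BLUP annual tau positivity change; the global
   accumulation rate is the mean across ROIs. The same machinery scores
   annual cognition change.
5. **Inference.** Standardized-beta OLS with covariates;
   shuffled-connectome exact permutation tests; sliding-window analysis
   of accumulation by hub-ratio stratum across the tau severity range,
   with a burden × ratio interaction model; seeded bootstrapped
   mediation (age → hub ratio → accumulation).

A synthetic-cohort generator (`cohort_config()`, `generate_connectome()`,
`generate_cohort()`) plants all of these effects with recorded ground
truth and drives the validation suite end-to-end.

## Worked example

```r
library(tauhub)

cfg    <- cohort_config(seed = 42L)          # 200 ROIs, 300 subjects
conn   <- generate_connectome(cfg)
cohort <- generate_cohort(cfg, conn)

hub  <- build_hub_map(conn$z, density = 0.3)
md   <- weighted_degree(distance_matrix(threshold_density(conn$z, 0.3)))
fits <- fit_cohort_gmms(cohort$scans, seed = 43L)
pos  <- positivity_matrix(cohort$scans, fits)
bp   <- positivity_wide(pos)                 # subject x ROI baseline

metrics <- subject_hub_metrics(bp, hub, md)
rates   <- annual_rates(pos)
metrics$global_rate <- global_summaries(bp, rates)$global_rate

d <- merge(metrics, cohort$covariates, by = "subject_id")
sym <- d[d$group %in% c("mci", "dementia"), ]
standardized_regression(sym, "tau_hub_ratio", "age",
                        c("sex", "education", "diagnosis"))
#> tau_hub_ratio ~ age (+ sex, education, diagnosis): beta_std = -0.392, p = 1.337e-06, n = 150

bootstrap_mediation(sym, "age", "tau_hub_ratio", "global_rate",
                    c("sex", "education", "diagnosis"),
                    n_boot = 10000, seed = 7)
#> mediation: ACME = -0.092 [-0.179, -0.021], p = 0.0068 (a = -0.392, b = 0.234, direct = -0.195, 10000 bootstraps)
```

Younger symptomatic subjects show a more hub-weighted tau pattern
(negative standardized age effect), and that pattern mediates the
association between younger age and faster tau accumulation (negative
indirect effect whose bootstrap CI excludes zero) — the planted structure
of the synthetic cohort, recovered by the pipeline.

`run_pipeline(config, out_dir)` chains every stage from a single config
(list or YAML), writes tidy CSV/TSV/JSON outputs plus a run manifest
(config hash, seeds, exclusion counts), and is byte-reproducible from
config + seed. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

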