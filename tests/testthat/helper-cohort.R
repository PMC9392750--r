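# Shared cohort machinery for recovery and acceptance tests.

# Reduced-size study used wherever a test repeats the full pipeline many
# times: same structure and planted effects as the default cohort, scaled
# to 60 ROIs and 135 subjects so that replicate studies stay cheap.
small_cohort_cfg <- function(seed = 1L, ...) {
  cohort_config(
    n_roi = 60L, n_hubs = 12L, n_seed_rois = 12L,
    group_sizes = c(cn_neg = 30L, preclinical = 30L, mci = 45L,
                    dementia = 30L),
    expected_affected = c(cn_neg = 0.2, preclinical = 2.5, mci = 9,
                          dementia = 12),
    seed = seed, ...)
}

# Full in-memory pipeline: simulate -> hub map -> positivity -> metrics ->
# rates -> battery. Returns the pieces the recovery tests assert on.
run_synthetic_pipeline <- function(cfg, n_boot = 1000L,
                                   with_mediation = TRUE) {
  conn <- generate_connectome(cfg)
  coh <- generate_cohort(cfg, conn)
  hub <- build_hub_map(conn$z, cfg$density)
  md <- weighted_degree(distance_matrix(threshold_density(conn$z,
                                                          cfg$density)))
  fits <- suppressMessages(fit_cohort_gmms(coh$scans, seed = cfg$seed + 1L))
  pos <- positivity_matrix(coh$scans, fits)
  bp <- positivity_wide(pos)
  rates <- annual_rates(pos)
  metrics <- subject_hub_metrics(bp, hub, md)
  gs <- global_summaries(bp, rates)
  metrics$global_rate <- gs$global_rate[match(metrics$subject_id,
                                              gs$subject_id)]
  cr <- cognition_rates(coh$cognition)
  metrics$cognition_rate <- unname(cr[metrics$subject_id])
  models <- analyze_cohort(metrics, coh$covariates)
  dm <- merge(metrics, coh$covariates, by = "subject_id")
  abpos <- dm[dm$group %in% c("preclinical", "mci", "dementia"), ]
  sympt <- dm[dm$group %in% c("mci", "dementia"), ]
  win <- sliding_window(abpos, "global_rate", c("sex", "education"))
  med <- if (with_mediation)
    bootstrap_mediation(sympt, "age", "tau_hub_ratio", "global_rate",
                        c("sex", "education", "diagnosis"),
                        n_boot = n_boot, seed = cfg$seed + 2L)
  else NULL
  list(conn = conn, cohort = coh, hub = hub, mean_distance = md,
       baseline_pos = bp, rates = rates, metrics = metrics,
       models = models, window = win, mediation = med,
       data = dm, sympt = sympt, abpos = abpos)
}

model_beta <- function(models, outcome, predictor, stratum) {
  r <- models[models$outcome == outcome & models$predictor == predictor &
                models$stratum == stratum, ]
  stopifnot(nrow(r) == 1)
  r
}

# The qualitative result pattern the planted cohort must reproduce:
# returns a named logical vector of the six directional checks.
pipeline_sign_pattern <- function(res) {
  m <- res$models
  c(age_ratio_sympt_neg =
      model_beta(m, "tau_hub_ratio", "age", "symptomatic")$beta_std < 0,
    age_ratio_preclin_null =
      model_beta(m, "tau_hub_ratio", "age", "preclinical")$p_value > 0.05,
    ratio_rate_pos =
      model_beta(m, "global_rate", "tau_hub_ratio",
                 "symptomatic")$beta_std > 0,
    age_rate_neg =
      model_beta(m, "global_rate", "age", "symptomatic")$beta_std < 0,
    acme_neg_ci = res$mediation$acme < 0 && res$mediation$ci_high < 0,
    rate_cognition_neg =
      model_beta(m, "cognition_rate", "global_rate", "all")$beta_std < 0,
    interaction_pos = res$window$interaction_beta > 0)
}
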