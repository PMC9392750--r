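# File formats, configuration and the pipeline orchestrator. All numeric
# text output is written at full double precision with '.' decimal
# separator, locale-independent, so a rerun from the same config and seeds
# is byte-identical.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

write_table_txt <- function(df, path, sep) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read / write a dense ROI x ROI matrix as CSV
#'
#' The CSV carries ROI ids as both header row and first column; reading
#' restores them as dimnames.
#'
#' @param m matrix with ROI-id dimnames.
#' @param path file path.
#' @return `read_matrix_csv` returns the matrix.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(roi_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_txt(df, path, sep = ",")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read / write a named per-ROI vector (hub map, mean distances) as CSV
#'
#' @param v named numeric vector.
#' @param path file path.
#' @param value_col name of the value column.
#' @return `read_roi_vector_csv` returns the named vector.
#' @export
write_roi_vector_csv <- function(v, path, value_col = "value") {
  df <- data.frame(roi_id = names(v), value = v, stringsAsFactors = FALSE)
  names(df)[2] <- value_col
  write_table_txt(df, path, sep = ",")
  invisible(path)
}

#' @rdname write_roi_vector_csv
#' @export
read_roi_vector_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read / write long-format tables (scans, cognition, metrics) as TSV
#'
#' @param df data frame.
#' @param path file path.
#' @return `read_tsv_table` returns the data frame.
#' @export
write_tsv_table <- function(df, path) {
  write_table_txt(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize / restore per-ROI mixture fits as TSV
#'
#' One row per ROI: selected k, component weights, means, SDs (two-component
#' columns `NA` where k = 1) and both AIC values.
#'
#' @param fits named list of `roi_gmm` objects.
#' @param path file path.
#' @return `read_gmm_tsv` returns the named list of `roi_gmm` objects.
#' @export
write_gmm_tsv <- function(fits, path) {
  pad <- function(v) if (length(v) == 2) v else c(v, NA_real_)
  df <- do.call(rbind, lapply(names(fits), function(r) {
    f <- fits[[r]]
    data.frame(roi_id = r, k = f$k_selected,
               w1 = pad(f$weights)[1], w2 = pad(f$weights)[2],
               m1 = pad(f$means)[1], m2 = pad(f$means)[2],
               s1 = pad(f$sds)[1], s2 = pad(f$sds)[2],
               separation = if (is.null(f$separation)) NA_real_
                            else f$separation,
               aic_k1 = f$aic_k1, aic_k2 = f$aic_k2,
               stringsAsFactors = FALSE)
  }))
  write_table_txt(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_gmm_tsv
#' @export
read_gmm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(df)), function(i) {
    k <- df$k[i]
    structure(list(
      k_selected = as.integer(k),
      weights = if (k == 2) c(df$w1[i], df$w2[i]) else df$w1[i],
      means = if (k == 2) c(df$m1[i], df$m2[i]) else df$m1[i],
      sds = if (k == 2) c(df$s1[i], df$s2[i]) else df$s1[i],
      separation = df$separation[i],
      aic_k1 = df$aic_k1[i], aic_k2 = df$aic_k2[i]), class = "roi_gmm")
  })
  stats::setNames(fits, df$roi_id)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the standard analysis battery on a scored cohort
#'
#' Fits the package's canonical standardized regressions: age vs. tau hub
#' ratio and vs. epicenter hub-ness (stratified by preclinical vs.
#' symptomatic status), age and hub ratio vs. the global tau accumulation
#' rate in symptomatic subjects, and accumulation vs. annual cognition
#' change. Covariates follow the stratum conventions: sex and education
#' everywhere, diagnosis (MCI = 0, dementia = 1) added in symptomatic
#' models, age added where it is not the predictor.
#'
#' @param metrics per-subject metric data frame (from
#'   [subject_hub_metrics()] merged with rates / cognition rates).
#' @param covariates per-subject covariate table with `group`, `age`, `sex`,
#'   `education`, `diagnosis`.
#' @return tidy data frame: one row per model with `outcome`, `predictor`,
#'   `stratum`, `beta_std`, `p_value`, `n`, `covariates`.
#' @export
analyze_cohort <- function(metrics, covariates) {
  d <- merge(metrics, covariates, by = "subject_id")
  sympt <- d[d$group %in% c("mci", "dementia"), ]
  precl <- d[d$group == "preclinical", ]
  spec <- list(
    list(sympt, "tau_hub_ratio", "age", c("sex", "education", "diagnosis"),
         "symptomatic"),
    list(precl, "tau_hub_ratio", "age", c("sex", "education"),
         "preclinical"),
    list(sympt, "epicenter_distance", "age",
         c("sex", "education", "diagnosis"), "symptomatic"),
    list(precl, "epicenter_distance", "age", c("sex", "education"),
         "preclinical"),
    list(sympt, "global_rate", "age", c("sex", "education", "diagnosis"),
         "symptomatic"),
    list(sympt, "global_rate", "tau_hub_ratio",
         c("age", "sex", "education", "diagnosis"), "symptomatic"))
  if ("cognition_rate" %in% names(d))
    spec <- c(spec, list(list(d, "cognition_rate", "global_rate",
                              c("age", "sex", "education"), "all")))
  rows <- lapply(spec, function(s) {
    res <- tryCatch(standardized_regression(s[[1]], s[[2]], s[[3]], s[[4]]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(outcome = s[[2]], predictor = s[[3]], stratum = s[[5]],
               beta_std = res$beta_std, p_value = res$p_value, n = res$n,
               covariates = paste(s[[4]], collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates: synthetic-cohort simulation (or reading supplied input
#' files), hub-map construction, mixture-model positivity scoring, tau hub
#' ratios and epicenters, mixed-model annual rates, the regression battery,
#' sliding-window analysis, bootstrapped mediation, and (optionally) the
#' shuffled-connectome exact test. Writes tidy text outputs plus a JSON run
#' manifest (config hash, seeds, exclusion counts) to `out_dir`. Reruns
#' from the same config are byte-identical.
#'
#' @param config either a list or a path to a YAML file. Recognized fields:
#'   `seed` (default 1), `density` (0.3), `epicenter_fraction` (0.1),
#'   `n_perm` (0 = skip the exact test), `n_boot` (default 10000),
#'   `simulate` (list of [cohort_config()] overrides; if absent, paths
#'   `connectivity_csv`, `scans_tsv`, `covariates_tsv`, and optionally
#'   `cognition_tsv` must be given).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results (`hub_map`,
#'   `metrics`, `models`, `window`, `mediation`, `exact_test`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  density <- config$density %||% 0.3
  epi_frac <- config$epicenter_fraction %||% 0.1
  n_perm <- as.integer(config$n_perm %||% 0L)
  n_boot <- as.integer(config$n_boot %||% 10000L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    cfg <- do.call(cohort_config, c(config$simulate, list(seed = seed)))
    conn <- generate_connectome(cfg)
    cohort <- generate_cohort(cfg, conn)
    z <- conn$z
    scans <- cohort$scans
    covariates <- cohort$covariates
    cognition <- cohort$cognition
    truth <- cohort$truth
    write_matrix_csv(z, file.path(out_dir, "connectivity.csv"))
    jsonlite::write_json(
      lapply(truth, function(x) if (is.numeric(x)) unname(x) else x),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  } else {
    z <- read_matrix_csv(config$connectivity_csv)
    scans <- read_tsv_table(config$scans_tsv)
    covariates <- read_tsv_table(config$covariates_tsv)
    cognition <- if (!is.null(config$cognition_tsv))
      read_tsv_table(config$cognition_tsv) else NULL
  }

  # hub map
  w <- threshold_density(z, density)
  md <- weighted_degree(distance_matrix(w))
  hub <- scale_hub_map(md)
  write_roi_vector_csv(hub, file.path(out_dir, "hub_map.csv"),
                       value_col = "scaled_hub")

  # positivity
  fits <- fit_cohort_gmms(scans, seed = seed + 1L)
  pos <- positivity_matrix(scans, fits)
  write_gmm_tsv(fits, file.path(out_dir, "gmm_fits.tsv"))
  write_tsv_table(pos, file.path(out_dir, "positivity.tsv"))
  bp <- positivity_wide(pos)

  # subject metrics
  metrics <- subject_hub_metrics(bp, hub, md, fraction = epi_frac)
  rates <- annual_rates(pos)
  gs <- global_summaries(bp, rates)
  metrics$global_rate <- gs$global_rate[match(metrics$subject_id,
                                              gs$subject_id)]
  if (!is.null(cognition)) {
    cr <- cognition_rates(cognition)
    metrics$cognition_rate <- unname(cr[metrics$subject_id])
  }
  write_tsv_table(metrics, file.path(out_dir, "subject_metrics.tsv"))
  epi <- attr(metrics, "epicenters")
  if (!is.null(epi))
    write_tsv_table(epi, file.path(out_dir, "epicenters.tsv"))

  # inference battery
  models <- analyze_cohort(metrics, covariates)
  write_tsv_table(models, file.path(out_dir, "models.tsv"))

  dm <- merge(metrics, covariates, by = "subject_id")
  abpos <- dm[dm$group %in% c("preclinical", "mci", "dementia"), ]
  sympt <- dm[dm$group %in% c("mci", "dementia"), ]
  win <- tryCatch(
    sliding_window(abpos, "global_rate",
                   covariates = c("sex", "education")),
    error = function(e) NULL)
  if (!is.null(win))
    write_tsv_table(win$windows, file.path(out_dir, "window.tsv"))
  med <- tryCatch(
    bootstrap_mediation(sympt, x = "age", m = "tau_hub_ratio",
                        y = "global_rate",
                        covariates = c("sex", "education", "diagnosis"),
                        n_boot = n_boot, seed = seed + 2L),
    error = function(e) NULL)
  if (!is.null(med))
    jsonlite::write_json(med[c("acme", "ci_low", "ci_high", "p_value",
                               "path_a", "path_b", "direct_effect",
                               "n", "n_boot")],
                         file.path(out_dir, "mediation.json"),
                         digits = NA, auto_unbox = TRUE)

  ex <- NULL
  if (n_perm > 0) {
    obs <- standardized_regression(sympt, "tau_hub_ratio", "age",
                                   c("sex", "education", "diagnosis"))
    nf <- shuffled_ratio_null(z, bp, sympt, "tau_hub_ratio", "age",
                              c("sex", "education", "diagnosis"),
                              density = density)
    ex <- exact_permutation_test(obs, nf, n_perm = n_perm, seed = seed + 3L)
    jsonlite::write_json(ex[c("p_value", "beta_obs", "n_perm", "n_redrawn")],
                         file.path(out_dir, "exact_test.json"),
                         digits = NA, auto_unbox = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tauhub")),
    config_hash = config_hash(config),
    seeds = list(pipeline = seed, gmm = seed + 1L, mediation = seed + 2L,
                 permutation = seed + 3L),
    density = density, epicenter_fraction = epi_frac,
    n_perm = n_perm, n_boot = n_boot,
    exclusions = list(
      single_visit_subjects = length(rates$excluded_subjects),
      zero_positivity_subjects = length(attr(metrics, "zero_subjects")),
      singular_rois = length(rates$singular_rois),
      shuffles_redrawn = if (is.null(ex)) 0L else ex$n_redrawn))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(hub_map = hub, mean_distance = md, metrics = metrics,
                 models = models, window = win, mediation = med,
                 exact_test = ex, truth = truth, manifest = manifest,
                 gmm_fits = fits, baseline_positivity = bp, rates = rates))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
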