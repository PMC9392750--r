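# Tau-PET SUVR -> tau positivity via per-ROI Gaussian mixture modelling,
# and longitudinal annual-change rates via linear mixed models.

# mclust resolves these helpers in the caller's frame, so they must be
# visible in this package's namespace.
#' @importFrom mclust mclustBIC meV
NULL

#' Fit a 1- vs 2-component Gaussian mixture to one ROI's SUVRs
#'
#' Flortaucipir off-target binding is approximately normal across subjects
#' while pathological (target) binding is right-shifted, so an affected ROI
#' shows a bimodal SUVR distribution. Both a single-Gaussian and an
#' unequal-variance two-Gaussian model are fitted by maximum likelihood
#' (the two-component fit takes the best of a model-based hierarchical
#' initialization plus seeded random restarts) and the winner is chosen by
#' AIC. Components of the two-component fit are ordered by ascending mean,
#' so component 2 is the pathological (right-most) distribution.
#'
#' The two-component model is only accepted when its components are
#' separated by at least `min_separation` pooled SDs: AIC alone endorses a
#' spurious split of unimodal data in roughly a tenth of samples, and such
#' overlapping components would score pure off-target noise as
#' tau-positive. Genuine off-target/target separation in SUVR data sits
#' far above this floor.
#'
#' @param suvrs numeric vector of one ROI's baseline SUVRs across subjects.
#' @param seed integer seed for the EM restarts.
#' @param min_n minimum sample size (default 20).
#' @param n_restarts number of random EM restarts for the k = 2 fit.
#' @param min_separation minimum component-mean separation in pooled-SD
#'   units for the two-component model to be eligible (default 2).
#' @return object of class `roi_gmm`: list with `k_selected` (1 or 2),
#'   `weights`, `means`, `sds` (length-`k_selected`), `separation`,
#'   `aic_k1`, `aic_k2`.
#' @export
fit_roi_gmm <- function(suvrs, seed = 1L, min_n = 20L, n_restarts = 5L,
                        min_separation = 2) {
  x <- as.numeric(suvrs)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("SUVRs must be finite and positive", call. = FALSE)
  if (length(x) < min_n)
    stop("need at least ", min_n, " subjects to fit a mixture (got ",
         length(x), ")", call. = FALSE)
  if (stats::sd(x) < 1e-12)
    stop("degenerate (constant) SUVR vector", call. = FALSE)

  n <- length(x)
  # k = 1 has a closed-form MLE.
  mu1 <- mean(x)
  sd1 <- sqrt(sum((x - mu1)^2) / n)
  ll1 <- sum(stats::dnorm(x, mu1, sd1, log = TRUE))
  aic1 <- 2 * 2 - 2 * ll1

  fits <- list()
  base <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (!is.null(base) && is.finite(base$loglik))
    fits[[length(fits) + 1L]] <- list(
      pro = base$parameters$pro,
      mean = as.numeric(base$parameters$mean),
      sd = sqrt(base$parameters$variance$sigmasq),
      loglik = base$loglik)
  restarts <- with_local_seed(seed, lapply(seq_len(n_restarts), function(i) {
    centers <- sort(sample(x, 2))
    zi <- cbind(stats::dnorm(x, centers[1], sd1 + 1e-6),
                stats::dnorm(x, centers[2], sd1 + 1e-6))
    zi <- zi / pmax(rowSums(zi), .Machine$double.xmin)
    tryCatch({
      f <- mclust::me(data = x, modelName = "V", z = zi)
      if (is.null(f$parameters) || !is.finite(f$loglik)) NULL else
        list(pro = f$parameters$pro,
             mean = as.numeric(f$parameters$mean),
             sd = sqrt(f$parameters$variance$sigmasq),
             loglik = f$loglik)
    }, error = function(e) NULL)
  }))
  fits <- c(fits, Filter(Negate(is.null), restarts))
  # Guard against spurious-singularity solutions (one component collapsing
  # onto a point mass drives the likelihood to +Inf without being a true MLE).
  fits <- Filter(function(f) all(f$sd > 1e-4 * sd1), fits)
  if (!length(fits)) {
    # every two-component solution collapsed onto a spurious singularity
    # (typically a handful of outlying subjects): no two-component MLE
    # exists, so the single Gaussian wins by default
    warning("two-component fit degenerate; falling back to k = 1",
            call. = FALSE)
    return(structure(list(k_selected = 1L, weights = 1, means = mu1,
                          sds = sd1, separation = NA_real_,
                          aic_k1 = aic1, aic_k2 = Inf),
                     class = "roi_gmm"))
  }
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  ord <- order(best$mean)
  aic2 <- 2 * 5 - 2 * best$loglik

  # component separation in pooled-SD units; AIC alone picks a spurious
  # two-component split of unimodal data in a non-trivial fraction of
  # samples, and such overlapping "components" would mark the upper half
  # of pure off-target noise as tau-positive
  sep <- diff(best$mean[ord]) / sqrt(mean(best$sd[ord]^2))
  k <- if (aic2 < aic1 && sep >= min_separation) 2L else 1L
  structure(list(
    k_selected = k,
    weights = if (k == 2L) best$pro[ord] else 1,
    means = if (k == 2L) best$mean[ord] else mu1,
    sds = if (k == 2L) best$sd[ord] else sd1,
    separation = sep,
    aic_k1 = aic1, aic_k2 = aic2), class = "roi_gmm")
}

#' @export
print.roi_gmm <- function(x, ...) {
  cat("ROI Gaussian mixture fit: k =", x$k_selected,
      sprintf("(AIC k1 = %.1f, k2 = %.1f)\n", x$aic_k1, x$aic_k2))
  cat("  means:", paste(sprintf("%.3f", x$means), collapse = ", "),
      " sds:", paste(sprintf("%.3f", x$sds), collapse = ", "),
      " weights:", paste(sprintf("%.2f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Tau positivity of a SUVR value under a mixture fit
#'
#' The posterior probability of the pathological (higher-mean) component,
#' multiplied by the SUVR itself — an SUVR score cleaned of the off-target
#' binding curve. SUVRs at or below the off-target component mean are
#' scored 0: with unequal component variances the wide pathological
#' component would otherwise dominate the far-left tail and mark
#' implausibly low uptake as tau-positive. If the single-component model
#' won the AIC comparison the ROI is treated as off-target only and
#' positivity is 0. Values below 1e-12 are floored to 0.
#'
#' @param suvr numeric vector of SUVR values (> 0).
#' @param fit `roi_gmm` object from [fit_roi_gmm()].
#' @return numeric vector of tau positivities (posterior-weighted SUVR).
#' @export
tau_positivity <- function(suvr, fit) {
  if (any(!is.finite(suvr)) || any(suvr <= 0))
    stop("SUVRs must be finite and positive", call. = FALSE)
  if (!inherits(fit, "roi_gmm")) stop("fit must be a roi_gmm", call. = FALSE)
  if (fit$k_selected == 1L) return(rep(0, length(suvr)))
  # log-scale posterior for numerical stability far in the tails
  l1 <- log(fit$weights[1]) + stats::dnorm(suvr, fit$means[1], fit$sds[1], log = TRUE)
  l2 <- log(fit$weights[2]) + stats::dnorm(suvr, fit$means[2], fit$sds[2], log = TRUE)
  post <- 1 / (1 + exp(l1 - l2))
  post[suvr <= fit$means[1]] <- 0
  p <- post * suvr
  p[p < 1e-12] <- 0
  p
}

check_scan_table <- function(scans) {
  need <- c("subject_id", "years_from_baseline", "roi_id", "suvr")
  miss <- setdiff(need, names(scans))
  if (length(miss))
    stop("scan table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(scans$suvr)) || any(scans$suvr <= 0))
    stop("scan table contains nonpositive or non-finite SUVRs", call. = FALSE)
  if (!any(scans$years_from_baseline == 0))
    stop("scan table has no baseline (years_from_baseline = 0) rows",
         call. = FALSE)
  invisible(scans)
}

#' Fit per-ROI mixtures on the baseline scans of a cohort
#'
#' Mixtures are fitted on baseline SUVRs only; the fitted parameters are
#' reused to score follow-up visits so that positivity stays comparable
#' over time.
#'
#' @param scans long-format scan table with columns `subject_id`,
#'   `years_from_baseline`, `roi_id`, `suvr`.
#' @param seed integer seed for the EM restarts.
#' @param min_n minimum baseline sample per ROI.
#' @return named list of `roi_gmm` fits, one per ROI.
#' @export
fit_cohort_gmms <- function(scans, seed = 1L, min_n = 20L) {
  check_scan_table(scans)
  base <- scans[scans$years_from_baseline == 0, ]
  by_roi <- split(base$suvr, as.character(base$roi_id))
  rois <- unique(as.character(base$roi_id))
  by_roi <- by_roi[rois]  # keep first-appearance ROI order
  fits <- vector("list", length(rois))
  names(fits) <- rois
  for (i in seq_along(rois)) {
    fits[[i]] <- suppressWarnings(
      fit_roi_gmm(by_roi[[i]], seed = seed + i, min_n = min_n))
  }
  k1 <- names(fits)[vapply(fits, `[[`, 0L, "k_selected") == 1L]
  if (length(k1))
    message(length(k1), " ROI(s) selected a single-component fit; ",
            "their positivity is scored 0")
  fits
}

#' Score a scan table into tau positivities
#'
#' Applies [tau_positivity()] element-wise using each ROI's baseline
#' mixture fit (all visits are scored with the baseline fit).
#'
#' @param scans long-format scan table (see [fit_cohort_gmms()]).
#' @param fits named list of `roi_gmm` fits covering every ROI in `scans`.
#' @return `scans` with an added `positivity` column.
#' @export
positivity_matrix <- function(scans, fits) {
  check_scan_table(scans)
  rois <- unique(as.character(scans$roi_id))
  miss <- setdiff(rois, names(fits))
  if (length(miss))
    stop("no mixture fit for ROI(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(scans$suvr)) || any(scans$suvr <= 0))
    stop("SUVRs must be finite and positive", call. = FALSE)
  # vectorized over the whole table via per-ROI parameter lookups
  par_of <- function(get) vapply(fits, get, 0)[as.character(scans$roi_id)]
  k2 <- par_of(function(f) f$k_selected) == 2
  w1 <- par_of(function(f) f$weights[1])
  w2 <- par_of(function(f) if (f$k_selected == 2) f$weights[2] else NA_real_)
  m1 <- par_of(function(f) f$means[1])
  m2 <- par_of(function(f) if (f$k_selected == 2) f$means[2] else NA_real_)
  s1 <- par_of(function(f) f$sds[1])
  s2 <- par_of(function(f) if (f$k_selected == 2) f$sds[2] else NA_real_)
  x <- scans$suvr
  p <- numeric(length(x))
  if (any(k2)) {
    l1 <- log(w1[k2]) + stats::dnorm(x[k2], m1[k2], s1[k2], log = TRUE)
    l2 <- log(w2[k2]) + stats::dnorm(x[k2], m2[k2], s2[k2], log = TRUE)
    post <- 1 / (1 + exp(l1 - l2))
    post[x[k2] <= m1[k2]] <- 0
    p[k2] <- post * x[k2]
  }
  p[p < 1e-12] <- 0
  scans$positivity <- p
  scans
}

#' Subject x ROI positivity matrix at one visit
#'
#' @param pos scored scan table from [positivity_matrix()].
#' @param years visit time to extract (default 0, baseline).
#' @return numeric matrix, rows = subjects, columns = ROIs.
#' @export
positivity_wide <- function(pos, years = 0) {
  v <- pos[pos$years_from_baseline == years, ]
  if (!nrow(v)) stop("no rows at years_from_baseline = ", years, call. = FALSE)
  subs <- unique(as.character(v$subject_id))
  rois <- unique(as.character(v$roi_id))
  m <- matrix(NA_real_, length(subs), length(rois),
              dimnames = list(subs, rois))
  m[cbind(as.character(v$subject_id), as.character(v$roi_id))] <- v$positivity
  if (anyNA(m)) stop("incomplete subject x ROI grid at this visit",
                     call. = FALSE)
  m
}

lmm_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    optCtrl = list(xtol_abs = 1e-6, ftol_abs = 1e-6))
}

# Resolve a fitted random-slope model: if singular, refit with the
# intercept-slope correlation dropped (when slope variance is real) or
# with a random intercept only; then extract per-subject BLUP slopes.
resolve_slope_fit <- function(fit, df, subs) {
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    # keep whichever variance components carry mass: a boundary fit can
    # mean a degenerate correlation, a zero slope variance, or (for
    # trajectories with a common origin) a zero intercept variance
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- function(v1) {
      x <- vc$vcov[vc$grp == "subject_id" & vc$var1 == v1 & is.na(vc$var2)]
      if (length(x) == 1 && is.finite(x)) x else 0
    }
    vfloor <- 1e-10 * stats::var(df$value)
    refit_with <- function(fml)
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = df, control = lmm_ctrl())))
    if (comp("years") > vfloor) {
      fit <- refit_with(value ~ years + (years || subject_id))
      if (lme4::isSingular(fit, tol = 1e-5)) {
        fit <- if (comp("(Intercept)") <= vfloor)
          refit_with(value ~ years + (0 + years | subject_id))
        else
          refit_with(value ~ years + (1 | subject_id))
        if (lme4::isSingular(fit, tol = 1e-5))
          fit <- refit_with(value ~ years + (1 | subject_id))
      }
    } else {
      fit <- refit_with(value ~ years + (1 | subject_id))
    }
  }
  fx <- lme4::fixef(fit)[["years"]]
  re <- lme4::ranef(fit)$subject_id
  rates <- stats::setNames(rep(fx, length(subs)), subs)
  if ("years" %in% colnames(re))
    rates[rownames(re)] <- fx + re[, "years"]
  list(rates = rates, fixed_slope = fx, singular = singular)
}

# Shared random-intercept + random-slope engine used for both per-ROI tau
# positivity trajectories and the cognition composite. Falls back to a
# random-intercept-only model when the full fit is singular.
fit_annual_slopes <- function(df, min_subjects = 10L) {
  df <- df[is.finite(df$value), ]
  nv <- table(df$subject_id)
  excluded <- names(nv)[nv < 2]
  df <- df[!(df$subject_id %in% excluded), ]
  subs <- unique(as.character(df$subject_id))
  if (!length(subs))
    stop("no subjects with at least 2 visits", call. = FALSE)
  if (length(subs) < min_subjects)
    stop("fewer than ", min_subjects, " subjects with repeat visits",
         call. = FALSE)
  if (stats::sd(df$value) < 1e-12) {
    return(list(rates = stats::setNames(rep(0, length(subs)), subs),
                fixed_slope = 0, singular = FALSE, constant = TRUE,
                excluded = excluded))
  }
  df$subject_id <- factor(df$subject_id)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ years + (years | subject_id), data = df,
               control = lmm_ctrl())))
  out <- resolve_slope_fit(fit, df, subs)
  c(out, list(constant = FALSE, excluded = excluded, fit = fit, data = df))
}

#' Per-subject annual tau positivity change rates
#'
#' For each ROI, fits a linear mixed model of tau positivity on years from
#' baseline with a subject-level random intercept and random slope; the
#' per-subject annual rate is the fixed slope plus the subject's predicted
#' (BLUP) random slope. ROIs whose random-slope fit is singular are refitted
#' with a random intercept only (those subjects then share the fixed slope)
#' and flagged. Subjects with a single visit are excluded and reported.
#'
#' @param pos scored scan table from [positivity_matrix()].
#' @param min_subjects minimum number of repeat-visit subjects per ROI model.
#' @return list with `rates` (subject x ROI matrix of annual positivity
#'   change), `global_rate` (per-subject mean across ROIs),
#'   `singular_rois`, `constant_rois`, and `excluded_subjects`.
#' @export
annual_rates <- function(pos, min_subjects = 10L) {
  if (!"positivity" %in% names(pos))
    stop("expected a scored scan table with a positivity column",
         call. = FALSE)
  nv <- tapply(pos$years_from_baseline, pos$subject_id,
               function(y) length(unique(y)))
  if (all(nv < 2)) stop("all subjects have a single visit", call. = FALSE)
  rois <- unique(as.character(pos$roi_id))
  idx_by_roi <- split(seq_len(nrow(pos)), as.character(pos$roi_id))[rois]
  res <- vector("list", length(rois))
  template <- NULL
  for (i in seq_along(rois)) {
    d <- pos[idx_by_roi[[i]], ]
    df <- data.frame(subject_id = as.character(d$subject_id),
                     years = d$years_from_baseline,
                     value = d$positivity)
    df <- df[order(df$subject_id, df$years), ]
    # every ROI model shares one design (same subjects, same visits), so
    # after the first full fit the remaining ROIs only swap the response
    if (!is.null(template) &&
        identical(df$subject_id, as.character(template$data$subject_id)) &&
        identical(df$years, template$data$years) &&
        stats::sd(df$value) >= 1e-12) {
      tdf <- template$data
      tdf$value <- df$value
      fit <- tryCatch(
        suppressMessages(suppressWarnings(lme4::refit(template$fit,
                                                      df$value))),
        error = function(e) NULL)
      res[[i]] <- if (is.null(fit))
        fit_annual_slopes(df, min_subjects)
      else
        c(resolve_slope_fit(fit, tdf, template$subs),
          list(constant = FALSE, excluded = template$excluded))
    } else {
      r <- fit_annual_slopes(df, min_subjects)
      if (is.null(template) && !r$constant && !length(r$excluded))
        template <- list(fit = r$fit, data = r$data,
                         subs = names(r$rates), excluded = r$excluded)
      res[[i]] <- r
    }
  }
  subs <- sort(unique(unlist(lapply(res, function(r) names(r$rates)))))
  rates <- matrix(NA_real_, length(subs), length(rois),
                  dimnames = list(subs, rois))
  for (i in seq_along(rois)) rates[names(res[[i]]$rates), i] <- res[[i]]$rates
  list(rates = rates,
       global_rate = rowMeans(rates),
       singular_rois = rois[vapply(res, `[[`, FALSE, "singular")],
       constant_rois = rois[vapply(res, `[[`, FALSE, "constant")],
       excluded_subjects = sort(unique(unlist(
         lapply(res, `[[`, "excluded")))))
}

#' Per-subject annual change rate of a cognition composite
#'
#' Applies the same random-intercept + random-slope mixed-model machinery
#' used for tau positivity trajectories to a longitudinal cognition score.
#'
#' @param cognition data frame with columns `subject_id`,
#'   `years_from_baseline`, `score`.
#' @param min_subjects minimum number of repeat-visit subjects.
#' @return named numeric vector of annual change rates (BLUP slopes).
#' @export
cognition_rates <- function(cognition, min_subjects = 10L) {
  need <- c("subject_id", "years_from_baseline", "score")
  if (!all(need %in% names(cognition)))
    stop("cognition table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fit_annual_slopes(
    data.frame(subject_id = cognition$subject_id,
               years = cognition$years_from_baseline,
               value = cognition$score), min_subjects)$rates
}

#' Global tau burden and accumulation rate per subject
#'
#' @param baseline_pos subject x ROI baseline positivity matrix
#'   (see [positivity_wide()]).
#' @param rates result of [annual_rates()], or `NULL` for baseline-only data.
#' @return data frame with `subject_id`, `global_tau` (mean baseline
#'   positivity across ROIs) and `global_rate` (mean annual ROI rate; `NA`
#'   for subjects without longitudinal data).
#' @export
global_summaries <- function(baseline_pos, rates = NULL) {
  out <- data.frame(subject_id = rownames(baseline_pos),
                    global_tau = rowMeans(baseline_pos),
                    global_rate = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(rates)) {
    gr <- rates$global_rate
    out$global_rate[match(names(gr), out$subject_id)] <- gr
  }
  rownames(out) <- NULL
  out
}
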