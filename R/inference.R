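# Statistical battery: standardized-beta OLS, shuffled-connectome exact
# tests, sliding-window interaction analysis, bootstrapped mediation.

#' Linear regression with standardized betas
#'
#' Ordinary least squares of `outcome` on `predictor` plus covariates, on
#' complete cases (listwise deletion, with the dropped count reported).
#' Regression weights are standardized as \eqn{\beta = b \,
#' \mathrm{SD}(x)/\mathrm{SD}(y)}; p values are two-sided from the t
#' distribution.
#'
#' @param data data frame holding all variables.
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate column names (may be
#'   empty). Binary covariates should be coded 0/1.
#' @return object of class `std_regression`: list with `beta_std` and
#'   `p_value` for the predictor, `n`, `n_dropped`, `betas` (all
#'   standardized coefficients), and the underlying `lm` fit.
#' @export
standardized_regression <- function(data, outcome, predictor,
                                    covariates = character()) {
  vars <- c(outcome, predictor, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variable(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data[, vars, drop = FALSE]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < length(vars) + 1)
    stop("too few complete cases (", nrow(d), ") for ", length(vars) - 1,
         " predictors", call. = FALSE)
  X <- as.matrix(d[, c(predictor, covariates), drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  b <- stats::coef(fit)[-1]
  sds <- apply(X, 2, stats::sd)
  beta_std <- b * sds / stats::sd(d[[outcome]])
  structure(list(
    outcome = outcome, predictor = predictor, covariates = covariates,
    beta_std = unname(beta_std[predictor]),
    p_value = sm[predictor, "Pr(>|t|)"],
    n = nrow(d), n_dropped = sum(!cc),
    betas = beta_std, fit = fit), class = "std_regression")
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s%s: beta_std = %.3f, p = %.4g, n = %d\n",
              x$outcome, x$predictor,
              if (length(x$covariates))
                paste0(" (+ ", paste(x$covariates, collapse = ", "), ")")
              else "",
              x$beta_std, x$p_value, x$n))
  invisible(x)
}

#' Exact permutation test against a null-pipeline distribution
#'
#' Compares an observed standardized beta against `n_perm` betas produced
#' by re-running the identical analysis under a null model (e.g., hub
#' ratios from shuffled connectomes). The two-sided exact p value is
#' \eqn{(1 + \#\{|\beta_{null}| \ge |\beta_{obs}|\}) / (1 + n_{perm})}.
#' A null iteration that fails (e.g., a shuffled connectome that
#' disconnects under thresholding) is redrawn with a fresh sub-seed and
#' counted.
#'
#' @param beta_obs observed standardized beta (or a `std_regression`).
#' @param null_fun function of one argument (an integer seed) returning one
#'   null beta.
#' @param n_perm number of null iterations (default 1000).
#' @param seed integer seed controlling the sub-seed stream.
#' @return list of class `exact_test`: `p_value`, `beta_obs`, `null_betas`,
#'   `n_perm`, `n_redrawn`, `seed`.
#' @export
exact_permutation_test <- function(beta_obs, null_fun, n_perm = 1000L,
                                   seed = 1L) {
  if (inherits(beta_obs, "std_regression")) beta_obs <- beta_obs$beta_std
  n_perm <- as.integer(n_perm)
  sub_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_perm + max(50L, n_perm)))
  nulls <- numeric(n_perm)
  used <- 0L
  redrawn <- 0L
  for (i in seq_len(n_perm)) {
    repeat {
      used <- used + 1L
      if (used > length(sub_seeds))
        stop("exhausted sub-seed pool; too many failing null iterations",
             call. = FALSE)
      val <- tryCatch(null_fun(sub_seeds[used]), error = function(e) NULL)
      if (!is.null(val) && is.finite(val)) break
      redrawn <- redrawn + 1L
    }
    nulls[i] <- val
  }
  p <- (1 + sum(abs(nulls) >= abs(beta_obs))) / (1 + n_perm)
  structure(list(p_value = p, beta_obs = beta_obs, null_betas = nulls,
                 n_perm = n_perm, n_redrawn = redrawn, seed = seed),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("exact test: beta_obs = %.3f, p = %.4g (%d permutations%s)\n",
              x$beta_obs, x$p_value, x$n_perm,
              if (x$n_redrawn) paste0(", ", x$n_redrawn, " redrawn") else ""))
  invisible(x)
}

#' Null-beta generator from shuffled connectomes
#'
#' Builds the `null_fun` for [exact_permutation_test()]: each call shuffles
#' the connectivity values, rebuilds the scaled hub map, recomputes every
#' subject's tau hub ratio, and re-runs the identical standardized
#' regression, returning the null beta.
#'
#' @param z group connectivity matrix.
#' @param baseline_pos subject x ROI baseline positivity matrix.
#' @param data covariate/metric data frame keyed by `subject_id`.
#' @param outcome,predictor,covariates regression specification; either
#'   `outcome` or `predictor` must be `ratio_var`.
#' @param ratio_var name of the hub-ratio column to be replaced by its null
#'   version (default `"tau_hub_ratio"`).
#' @param density edge density for thresholding (default 0.3).
#' @return function(seed) -> null standardized beta.
#' @export
shuffled_ratio_null <- function(z, baseline_pos, data, outcome, predictor,
                                covariates = character(),
                                ratio_var = "tau_hub_ratio",
                                density = 0.3) {
  if (!ratio_var %in% c(outcome, predictor))
    stop("ratio_var must be the outcome or the predictor", call. = FALSE)
  # fixed pieces are prepared once; each null draw only rebuilds the hub
  # map and re-evaluates the identical OLS (via the Frisch-Waugh identity,
  # which gives the same standardized beta as the full regression)
  fixed_vars <- setdiff(c(outcome, predictor, covariates), ratio_var)
  nz <- rownames(baseline_pos)[rowSums(baseline_pos) > 0]
  d0 <- data[match(nz, data$subject_id), c("subject_id", fixed_vars),
             drop = FALSE]
  keep <- stats::complete.cases(d0)
  d0 <- d0[keep, , drop = FALSE]
  bp <- baseline_pos[d0$subject_id, colnames(baseline_pos), drop = FALSE]
  tot <- rowSums(bp)
  other <- if (ratio_var == outcome) predictor else outcome
  C <- cbind(rep(1, nrow(d0)),
             if (length(covariates))
               as.matrix(d0[, covariates, drop = FALSE]) else NULL)
  qrC <- qr(C)
  r_other <- qr.resid(qrC, d0[[other]])
  sd_other <- stats::sd(d0[[other]])
  ratio_is_outcome <- ratio_var == outcome
  function(seed) {
    hub0 <- build_hub_map(shuffle_connectome(z, seed), density)
    ratio <- as.vector(bp %*% hub0[colnames(bp)]) / tot
    r_ratio <- qr.resid(qrC, ratio)
    if (ratio_is_outcome) {
      b <- sum(r_other * r_ratio) / sum(r_other^2)
      b * sd_other / stats::sd(ratio)
    } else {
      b <- sum(r_ratio * r_other) / sum(r_ratio^2)
      b * stats::sd(ratio) / sd_other
    }
  }
}

#' Sliding-window analysis of outcome vs. tau burden, by hub-ratio stratum
#'
#' Sorts subjects by global tau, slides a window of `window_frac` of the
#' sample in steps of `step` subjects, and within each window reports the
#' mean outcome separately for subjects above vs. below the full-sample
#' median tau hub ratio. The global tau x hub ratio interaction on the
#' outcome is tested by OLS with standardized coefficients.
#'
#' @param data data frame with `global_tau`, the hub-ratio column, the
#'   outcome, and covariates; complete cases are used.
#' @param outcome outcome column name (e.g., `"global_rate"` or `"age"`).
#' @param covariates covariate column names for the interaction model.
#' @param window_frac window size as a fraction of the sample (default 0.30).
#' @param step window shift in subjects (default 3).
#' @param ratio_var hub-ratio column name.
#' @return list of class `sliding_window`: `windows` data frame (one row per
#'   window: mean global tau, stratum means, stratum ns), `interaction_beta`,
#'   `interaction_p`, `median_ratio`, `n`.
#' @export
sliding_window <- function(data, outcome, covariates = character(),
                           window_frac = 0.30, step = 3L,
                           ratio_var = "tau_hub_ratio") {
  vars <- c("global_tau", ratio_var, outcome, covariates)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  n <- nrow(d)
  w <- round(window_frac * n)
  if (w < 10 || n < w)
    stop("window of ", w, " subjects is too small (need >= 10, n = ", n, ")",
         call. = FALSE)
  d <- d[order(d$global_tau), , drop = FALSE]
  med <- stats::median(d[[ratio_var]])
  high <- d[[ratio_var]] > med
  starts <- seq(1L, n - w + 1L, by = step)
  windows <- do.call(rbind, lapply(starts, function(s) {
    idx <- s:(s + w - 1L)
    hi <- idx[high[idx]]; lo <- idx[!high[idx]]
    data.frame(
      window_start = s,
      mean_global_tau = mean(d$global_tau[idx]),
      mean_outcome_high = if (length(hi)) mean(d[[outcome]][hi]) else NA_real_,
      mean_outcome_low = if (length(lo)) mean(d[[outcome]][lo]) else NA_real_,
      n_high = length(hi), n_low = length(lo))
  }))
  # interaction model on the full sample, standardized coefficients
  d$.inter <- d$global_tau * d[[ratio_var]]
  fml <- stats::reformulate(c("global_tau", ratio_var, covariates, ".inter"),
                            response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  b <- stats::coef(fit)[".inter"]
  beta <- unname(b * stats::sd(d$.inter) / stats::sd(d[[outcome]]))
  structure(list(windows = windows,
                 interaction_beta = beta,
                 interaction_p = sm[".inter", "Pr(>|t|)"],
                 median_ratio = med, n = n,
                 window_size = w, step = step),
            class = "sliding_window")
}

#' @export
print.sliding_window <- function(x, ...) {
  cat(sprintf(paste0("sliding window: %d windows of %d subjects (step %d); ",
                     "interaction beta = %.3f, p = %.4g\n"),
              nrow(x$windows), x$window_size, x$step,
              x$interaction_beta, x$interaction_p))
  invisible(x)
}

#' Bootstrapped mediation analysis
#'
#' Tests whether the effect of `x` on `y` is mediated by `m`, controlling
#' all paths for the covariates. Variables `x`, `m`, `y` are standardized;
#' path a is the coefficient of `x` in `m ~ x + covariates`, path b and the
#' direct effect come from `y ~ x + m + covariates`, and the average
#' mediated (indirect) effect is `a * b`. Inference is by seeded case-
#' resampling bootstrap with a percentile confidence interval; the p value
#' is the two-sided bootstrap tail proportion of the indirect effect about
#' zero. Degenerate resamples (rank-deficient design) are redrawn with a
#' fresh sub-seed.
#'
#' @param data data frame with all variables; complete cases are used.
#' @param x,m,y column names of predictor, mediator, outcome.
#' @param covariates covariate column names for every path.
#' @param n_boot number of bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list of class `mediation_result`: `acme`, `ci_low`, `ci_high`,
#'   `p_value`, `path_a`, `path_b`, `direct_effect`, `n`, `n_boot`, `seed`,
#'   `boot_acme` (the bootstrap distribution).
#' @export
bootstrap_mediation <- function(data, x, m, y, covariates = character(),
                                n_boot = 10000L, seed = 1L, conf = 0.95) {
  vars <- c(x, m, y, covariates)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]),
            vars, drop = FALSE]
  n <- nrow(d)
  if (n < 20) stop("fewer than 20 complete cases", call. = FALSE)
  if (n_boot < 1000) stop("n_boot must be at least 1000", call. = FALSE)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  d[[x]] <- zs(d[[x]]); d[[m]] <- zs(d[[m]]); d[[y]] <- zs(d[[y]])
  C <- if (length(covariates))
    as.matrix(d[, covariates, drop = FALSE]) else NULL
  Xa <- cbind(1, d[[x]], C)                 # m ~ x + covs; a = coef 2
  Xb <- cbind(1, d[[x]], d[[m]], C)         # y ~ x + m + covs; b = coef 3
  mv <- d[[m]]; yv <- d[[y]]
  coef_of <- function(fit, j) {
    # .lm.fit pivots near-collinear columns; map back to input order
    unname(fit$coefficients[match(j, fit$pivot)])
  }
  fa0 <- stats::.lm.fit(Xa, mv)
  fb0 <- stats::.lm.fit(Xb, yv)
  a_hat <- coef_of(fa0, 2)
  b_hat <- coef_of(fb0, 3)
  direct <- coef_of(fb0, 2)

  boot <- numeric(n_boot)
  redrawn <- 0L
  with_local_seed(seed, for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fa <- stats::.lm.fit(Xa[idx, , drop = FALSE], mv[idx])
      fb <- stats::.lm.fit(Xb[idx, , drop = FALSE], yv[idx])
      if (fa$rank == ncol(Xa) && fb$rank == ncol(Xb)) break
      redrawn <- redrawn + 1L
    }
    boot[i] <- coef_of(fa, 2) * coef_of(fb, 3)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(p, 1)
  structure(list(acme = a_hat * b_hat,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 path_a = a_hat, path_b = b_hat,
                 direct_effect = direct,
                 n = n, n_boot = n_boot, seed = seed,
                 n_redrawn = redrawn,
                 boot_acme = boot), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("mediation: ACME = %.3f [%.3f, %.3f], p = %.4g ",
                     "(a = %.3f, b = %.3f, direct = %.3f, %d bootstraps)\n"),
              x$acme, x$ci_low, x$ci_high, x$p_value,
              x$path_a, x$path_b, x$direct_effect, x$n_boot))
  invisible(x)
}
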