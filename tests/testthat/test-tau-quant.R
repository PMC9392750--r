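test_that("the mixture model recovers a planted bimodal SUVR distribution", {
  set.seed(401)
  x <- c(rnorm(350, 1.10, 0.05), rnorm(150, 1.60, 0.20))
  fit <- fit_roi_gmm(x, seed = 1)
  expect_identical(fit$k_selected, 2L)
  expect_lt(abs(fit$means[1] - 1.10), 0.05)
  expect_lt(abs(fit$means[2] - 1.60), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  expect_lt(fit$aic_k2, fit$aic_k1)
})

test_that("unimodal SUVRs select the single-component model", {
  hits <- vapply(1:20, function(i) {
    set.seed(410 + i)
    x <- rnorm(500, 1.10, 0.05)
    fit_roi_gmm(x, seed = i)$k_selected == 1L
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("degenerate and undersized SUVR inputs error", {
  expect_error(fit_roi_gmm(rep(1.1, 100)), "constant")
  expect_error(fit_roi_gmm(rnorm(10, 1.1, 0.05)), "at least 20")
  expect_error(fit_roi_gmm(c(rnorm(99, 1.1, 0.1), -1)), "positive")
})

test_that("tau positivity is the pathological posterior times SUVR", {
  set.seed(402)
  x <- c(rnorm(350, 1.10, 0.05), rnorm(150, 1.60, 0.20))
  fit <- fit_roi_gmm(x, seed = 1)

  # direct Bayes-rule evaluation as the oracle
  post <- function(s) {
    d1 <- fit$weights[1] * dnorm(s, fit$means[1], fit$sds[1])
    d2 <- fit$weights[2] * dnorm(s, fit$means[2], fit$sds[2])
    d2 / (d1 + d2)
  }
  expect_gt(post(2.5), 0.999)
  expect_equal(tau_positivity(2.5, fit), post(2.5) * 2.5, tolerance = 1e-9)
  expect_equal(tau_positivity(0.8, fit), 0)  # far left: floored to 0

  grid <- seq(0.9, 2.5, by = 0.01)
  p <- tau_positivity(grid, fit)
  expect_true(all(diff(p) >= -1e-12))       # monotone in SUVR
  expect_true(all(p <= grid + 1e-12))       # posterior <= 1

  k1 <- fit_roi_gmm(rnorm(500, 1.1, 0.05), seed = 3)
  if (k1$k_selected == 1L)
    expect_equal(tau_positivity(c(1.0, 1.8, 3.0), k1), c(0, 0, 0))
  expect_error(tau_positivity(-1, fit), "positive")
})

test_that("cohort scoring covers every ROI and respects the SUVR bound", {
  cfg <- small_cohort_cfg(seed = 420L)
  coh <- generate_cohort(cfg, generate_connectome(cfg))
  fits <- suppressMessages(fit_cohort_gmms(coh$scans, seed = 421L))
  pos <- positivity_matrix(coh$scans, fits)
  expect_true(all(pos$positivity >= 0))
  expect_true(all(pos$positivity <= pos$suvr + 1e-9))
  bp <- positivity_wide(pos)
  expect_identical(dim(bp), c(sum(cfg$group_sizes), cfg$n_roi))

  # ROIs simulated without any target component stay essentially at zero
  untouched <- setdiff(colnames(bp),
                       c(coh$truth$hub_rois, coh$truth$seed_rois))
  base <- coh$scans[coh$scans$years_from_baseline == 0, ]
  expect_lt(median(bp[, untouched]), 0.05 * median(base$suvr))

  expect_error(positivity_matrix(coh$scans, fits[-1]), "no mixture fit")
})

test_that("noiseless linear trajectories are recovered exactly", {
  set.seed(430)
  n <- 40
  a <- rnorm(n, 0.1, 0.05)
  b <- rnorm(n, 0.02, 0.01)
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 3),
                  years_from_baseline = rep(c(0, 1, 2), n),
                  roi_id = "roi_001")
  d$positivity <- a[rep(1:n, each = 3)] +
    b[rep(1:n, each = 3)] * d$years_from_baseline
  r <- annual_rates(d)
  expect_equal(unname(r$rates[sprintf("s%02d", 1:n), 1]), b,
               tolerance = 1e-6)
  expect_equal(unname(r$global_rate[sprintf("s%02d", 1:n)]), b,
               tolerance = 1e-6)
})

test_that("mixed-model rates recover planted slopes under noise", {
  set.seed(431)
  n <- 100
  b <- rnorm(n, 0.02, 0.01)
  a <- rnorm(n, 0.1, 0.05)
  mk <- function(k) {
    d <- data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = 3),
                    years_from_baseline = rep(c(0, 1, 2), n),
                    roi_id = sprintf("roi_%03d", k))
    d$positivity <- a[rep(1:n, each = 3)] +
      b[rep(1:n, each = 3)] * d$years_from_baseline + rnorm(3 * n, 0, 0.01)
    d
  }
  # one trajectory per subject: correlation is information-bounded at
  # tau / sqrt(tau^2 + sigma^2/2) ~= 0.82
  r1 <- annual_rates(mk(1))
  expect_gt(cor(b, r1$rates[sprintf("s%03d", 1:n), 1]), 0.75)
  # the per-subject global rate pools ROI models and clears 0.9
  r10 <- annual_rates(do.call(rbind, lapply(1:10, mk)))
  expect_gt(cor(b, r10$global_rate[sprintf("s%03d", 1:n)]), 0.9)
})

test_that("BLUP slopes shrink toward the fixed slope as noise grows", {
  set.seed(432)
  n <- 80
  b <- rnorm(n, 0.02, 0.01)
  shrink_ratio <- function(sd_eps) {
    d <- data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = 3),
                    years_from_baseline = rep(c(0, 1, 2), n),
                    roi_id = "roi_001")
    d$positivity <- 0.1 + b[rep(1:n, each = 3)] * d$years_from_baseline +
      rnorm(3 * n, 0, sd_eps)
    blup <- annual_rates(d)$rates[, 1]
    # per-subject OLS slopes as the unshrunken reference
    ols <- vapply(split(d, d$subject_id), function(s)
      coef(lm(positivity ~ years_from_baseline, s))[2], 0)
    sd(blup) / sd(ols)
  }
  expect_lt(shrink_ratio(0.05), shrink_ratio(0.005))
})

test_that("single-visit subjects are excluded and reported", {
  set.seed(433)
  n <- 30
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 3),
                  years_from_baseline = rep(c(0, 1, 2), n),
                  roi_id = "roi_001")
  d$positivity <- 0.1 + 0.02 * d$years_from_baseline + rnorm(3 * n, 0, 0.01)
  d <- d[!(d$subject_id == "s01" & d$years_from_baseline > 0), ]
  r <- annual_rates(d)
  expect_identical(r$excluded_subjects, "s01")
  expect_false("s01" %in% rownames(r$rates))
  dd <- d[d$years_from_baseline == 0, ]
  expect_error(annual_rates(dd), "single visit")
})

test_that("global summaries are row means of positivity and rates", {
  bp <- matrix(c(0.2, 0.2, 0.1, 0.3), 2, 2,
               dimnames = list(c("s1", "s2"), c("r1", "r2")))
  gs <- global_summaries(bp)
  expect_equal(gs$global_tau, c(0.15, 0.25))
  rates <- list(global_rate = c(s1 = 0.02, s2 = 0.01))
  gs2 <- global_summaries(bp, rates)
  expect_equal(gs2$global_rate, c(0.02, 0.01))
  # brute-force oracle
  set.seed(434)
  m <- matrix(runif(50), 5, 10,
              dimnames = list(paste0("s", 1:5), paste0("r", 1:10)))
  expect_equal(global_summaries(m)$global_tau,
               unname(apply(m, 1, function(x) sum(x) / length(x))))
})

test_that("cognition change rates recover planted decline slopes", {
  cfg <- small_cohort_cfg(seed = 440L)
  coh <- generate_cohort(cfg, generate_connectome(cfg))
  cr <- cognition_rates(coh$cognition)
  expect_gt(cor(coh$truth$true_cognition_rate[names(cr)], cr), 0.9)
})
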