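test_that("standardized betas match closed forms and partial regression", {
  set.seed(601)
  d <- data.frame(x = rnorm(50))
  d$y <- d$x
  r <- standardized_regression(d, "y", "x")
  expect_equal(r$beta_std, 1, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-12)

  # y = 0.5 x + e with Var(e) = 0.75 gives standardized slope 0.5
  set.seed(602)
  n <- 2000
  d2 <- data.frame(x = rnorm(n))
  d2$y <- 0.5 * d2$x + rnorm(n, 0, sqrt(0.75))
  r2 <- standardized_regression(d2, "y", "x")
  expect_lt(abs(r2$beta_std - 0.5), 0.04)

  # Frisch-Waugh: beta of x adjusting for binary g equals the slope of
  # residualized y on residualized x, standardized with the raw SDs
  set.seed(603)
  d3 <- data.frame(x = rnorm(120), g = rbinom(120, 1, 0.4))
  d3$y <- 0.3 * d3$x + 0.8 * d3$g + rnorm(120)
  r3 <- standardized_regression(d3, "y", "x", covariates = "g")
  rx <- resid(lm(x ~ g, d3)); ry <- resid(lm(y ~ g, d3))
  b_fw <- sum(rx * ry) / sum(rx^2)
  expect_equal(r3$beta_std, b_fw * sd(d3$x) / sd(d3$y), tolerance = 1e-10)
})

test_that("standardized betas are invariant to affine rescaling", {
  set.seed(604)
  d <- data.frame(x = rnorm(80), c1 = rnorm(80))
  d$y <- 0.4 * d$x + 0.2 * d$c1 + rnorm(80)
  r <- standardized_regression(d, "y", "x", "c1")
  d2 <- data.frame(x = 3.2 * d$x - 7, c1 = 0.1 * d$c1 + 2, y = 100 * d$y + 5)
  r2 <- standardized_regression(d2, "y", "x", "c1")
  expect_equal(r2$beta_std, r$beta_std, tolerance = 1e-9)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-9)
})

test_that("degenerate regression designs error informatively", {
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  d$x2 <- 2 * d$x
  expect_error(standardized_regression(d, "y", "x", "x2"), "collinear")
  expect_error(standardized_regression(d, "y", "nope"), "not in data")
  d$z <- NA_real_
  expect_error(standardized_regression(d, "y", "x", "z"), "complete cases")
})

test_that("exact permutation p values follow the +1-corrected formula", {
  nulls <- seq(0.001, 0.199, length.out = 199)
  nf <- local({ i <- 0; function(seed) { i <<- i + 1; nulls[i] } })
  r <- exact_permutation_test(1.0, nf, n_perm = 199, seed = 1)
  expect_equal(r$p_value, 1 / 200)

  nf0 <- local({ i <- 0; function(seed) { i <<- i + 1; nulls[i] } })
  r0 <- exact_permutation_test(0, nf0, n_perm = 199, seed = 1)
  expect_equal(r0$p_value, 1)

  # failing iterations are redrawn with fresh sub-seeds and counted
  flaky <- local({
    i <- 0
    function(seed) { i <<- i + 1; if (i %% 5 == 0) stop("boom"); 0.01 }
  })
  rf <- exact_permutation_test(1, flaky, n_perm = 40, seed = 2)
  expect_identical(rf$n_perm, 40L)
  expect_gt(rf$n_redrawn, 0)
  expect_length(rf$null_betas, 40)
})

test_that("shuffled-connectome nulls flatten a real hub-age association", {
  cfg <- small_cohort_cfg(seed = 610L)
  conn <- generate_connectome(cfg)
  hub <- build_hub_map(conn$z, cfg$density)
  set.seed(611)
  n <- 80
  age <- rnorm(n, 74, 7)
  # hub-weighted positivity increasing for younger subjects
  lam <- pmin(pmax(0.5 - 0.3 * as.numeric(scale(age)) + rnorm(n, 0, 0.1),
                   0), 1)
  bp <- t(vapply(seq_len(n), function(s) {
    p <- rep(0.01, cfg$n_roi)
    hub_idx <- match(conn$truth$hub_rois, names(hub))
    seed_idx <- match(conn$truth$seed_rois, names(hub))
    p[hub_idx] <- p[hub_idx] + lam[s] * rexp(length(hub_idx))
    p[seed_idx] <- p[seed_idx] + (1 - lam[s]) * rexp(length(seed_idx))
    p
  }, numeric(cfg$n_roi)))
  dimnames(bp) <- list(sprintf("s%03d", 1:n), names(hub))
  d <- data.frame(subject_id = rownames(bp), age = age,
                  sex = rbinom(n, 1, 0.5), education = rnorm(n, 16, 2))
  d$tau_hub_ratio <- vapply(seq_len(n),
                            function(s) tau_hub_ratio(bp[s, ], hub), 0)
  obs <- standardized_regression(d, "tau_hub_ratio", "age",
                                 c("sex", "education"))
  nf <- shuffled_ratio_null(conn$z, bp, d, "tau_hub_ratio", "age",
                            c("sex", "education"), density = cfg$density)
  ex <- exact_permutation_test(obs, nf, n_perm = 99, seed = 612)
  expect_lt(obs$beta_std, -0.3)
  expect_lt(ex$p_value, 0.05)
  expect_lt(abs(mean(ex$null_betas)), abs(obs$beta_std) / 2)

  # the null generator's fast path computes the very same standardized
  # beta as running the full regression on the shuffled-connectome ratio
  hub0 <- build_hub_map(shuffle_connectome(conn$z, 4242L), cfg$density)
  d2 <- d
  d2$tau_hub_ratio <- vapply(seq_len(n),
                             function(s) tau_hub_ratio(bp[s, ], hub0), 0)
  full <- standardized_regression(d2, "tau_hub_ratio", "age",
                                  c("sex", "education"))
  expect_equal(nf(4242L), full$beta_std, tolerance = 1e-10)

  # and identically when the ratio is the predictor
  d3 <- d2
  set.seed(613)
  d3$global_rate <- 0.02 * d3$tau_hub_ratio + rnorm(n, 0, 0.02)
  nf2 <- shuffled_ratio_null(conn$z, bp, d3, "global_rate",
                             "tau_hub_ratio", c("sex", "education"),
                             density = cfg$density)
  full2 <- standardized_regression(d3, "global_rate", "tau_hub_ratio",
                                   c("sex", "education"))
  d4 <- d3
  hub1 <- build_hub_map(shuffle_connectome(conn$z, 99L), cfg$density)
  d4$tau_hub_ratio <- vapply(seq_len(n),
                             function(s) tau_hub_ratio(bp[s, ], hub1), 0)
  full_null <- standardized_regression(d4, "global_rate", "tau_hub_ratio",
                                       c("sex", "education"))
  expect_equal(nf2(99L), full_null$beta_std, tolerance = 1e-10)
})

test_that("sliding windows are counted and stratified as specified", {
  set.seed(620)
  n <- 100
  d <- data.frame(global_tau = runif(n), tau_hub_ratio = rnorm(n),
                  outcome = rnorm(n))
  r <- sliding_window(d, "outcome", window_frac = 0.30, step = 3L)
  expect_equal(r$window_size, 30)
  expect_equal(nrow(r$windows), floor((n - 30) / 3) + 1)  # 24
  expect_true(all(diff(r$windows$mean_global_tau) > 0))
  expect_true(all(r$windows$n_high + r$windows$n_low == 30))

  # a window whose stratum is empty reports NA, not a dropped window
  d2 <- d
  d2$tau_hub_ratio <- d2$global_tau  # strata perfectly split along tau
  r2 <- sliding_window(d2, "outcome", window_frac = 0.30, step = 3L)
  expect_true(anyNA(r2$windows$mean_outcome_high) ||
                anyNA(r2$windows$mean_outcome_low))
  expect_identical(nrow(r2$windows), nrow(r$windows))
})

test_that("interaction p values are calibrated under the null and powered
           under a planted interaction", {
  # null: outcome unrelated to the hub ratio
  set.seed(621)
  pvals <- vapply(1:150, function(i) {
    n <- 80
    d <- data.frame(global_tau = rnorm(n), tau_hub_ratio = rnorm(n),
                    outcome = rnorm(n))
    sliding_window(d, "outcome")$interaction_p
  }, 0)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  # power: standardized interaction 0.3 at n = 150, unit noise
  set.seed(622)
  hits <- vapply(1:100, function(i) {
    n <- 150
    x1 <- rnorm(n); x2 <- rnorm(n)
    pr <- x1 * x2
    y <- 0.3 * pr / sd(pr) + rnorm(n, 0, sqrt(1 - 0.09))
    d <- data.frame(global_tau = x1, tau_hub_ratio = x2, outcome = y)
    r <- sliding_window(d, "outcome")
    r$interaction_beta > 0 && r$interaction_p < 0.05
  }, TRUE)
  expect_gte(sum(hits), 80)
})

test_that("bootstrapped mediation recovers a planted indirect effect", {
  set.seed(630)
  n <- 200
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n, 0, sqrt(1 - 0.25))
  y <- 0.4 * m + rnorm(n, 0, sqrt(1 - 0.16))
  d <- data.frame(x = x, m = m, y = y)
  r <- bootstrap_mediation(d, "x", "m", "y", n_boot = 2000, seed = 7)
  expect_lt(abs(r$acme - 0.20), 0.07)
  expect_gt(r$ci_low, 0)
  expect_lte(r$ci_low, r$acme)
  expect_gte(r$ci_high, r$acme)
  expect_lt(r$p_value, 0.05)
  expect_lt(abs(r$direct_effect), 0.15)

  # determinism: identical seed, identical result
  r2 <- bootstrap_mediation(d, "x", "m", "y", n_boot = 2000, seed = 7)
  expect_identical(r$acme, r2$acme)
  expect_identical(r$boot_acme, r2$boot_acme)
  expect_identical(c(r$ci_low, r$ci_high), c(r2$ci_low, r2$ci_high))
})

test_that("a null b path yields confidence intervals covering zero", {
  covered <- vapply(1:20, function(i) {
    set.seed(640 + i)
    n <- 150
    x <- rnorm(n)
    m <- 0.5 * x + rnorm(n, 0, sqrt(0.75))
    y <- rnorm(n)  # b = 0 by construction
    d <- data.frame(x = x, m = m, y = y)
    r <- bootstrap_mediation(d, "x", "m", "y", n_boot = 1000, seed = i)
    r$ci_low <= 0 && r$ci_high >= 0
  }, TRUE)
  expect_gte(sum(covered), 18)
})

test_that("mediation enforces its preconditions", {
  d <- data.frame(x = rnorm(10), m = rnorm(10), y = rnorm(10))
  expect_error(bootstrap_mediation(d, "x", "m", "y"), "20")
  d2 <- data.frame(x = rnorm(50), m = rnorm(50), y = rnorm(50))
  expect_error(bootstrap_mediation(d2, "x", "m", "y", n_boot = 100), "1000")
})
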