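study_sizes <- function(n_case, n_control) {
  list(n_case = n_case, n_control = n_control)
}

make_estimates <- function(beta, se, ids = sprintf("s%d", seq_along(beta)),
                           n_case = NULL, n_control = NULL) {
  out <- tibble::tibble(
    exposure_id = "activity", outcome_id = "cancer", study_id = ids,
    method = "wald", n_snps = 1L, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    Q = NA_real_, Q_df = NA_real_, Q_pval = NA_real_)
  if (!is.null(n_case)) {
    out$n_case <- n_case; out$n_control <- n_control
  }
  out
}

test_that("overlap correlation is 0 with no sharing and ~1 for a study against itself", {
  a <- study_sizes(10000, 10000)
  expect_equal(overlap_correlation(a, a, 0, 0), 0)
  expect_equal(overlap_correlation(a, a, 10000, 10000), 0.99)  # clipped at 1
  expect_error(overlap_correlation(a, a, 10001, 0),
               class = "ratiomr_validation_error")
  # balanced studies sharing half the controls: r = s/N
  expect_equal(overlap_correlation(a, a, 5000, 0), 0.25, tolerance = 1e-12)
})

test_that("fixed-effects pooling with zero overlap reproduces classical IVW exactly", {
  est <- make_estimates(c(0.08, 0.12, 0.05), c(0.02, 0.05, 0.03))
  pooled <- meta_fixed(est)
  w <- 1 / est$se^2
  expect_equal(pooled$beta, sum(w * est$beta) / sum(w), tolerance = 1e-12)
  expect_equal(pooled$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # single study passes through; identical replicates shrink by sqrt(2)
  expect_equal(meta_fixed(est[1, ])$beta, est$beta[1])
  dup <- make_estimates(c(0.1, 0.1), c(0.02, 0.02))
  expect_equal(meta_fixed(dup)$se, 0.02 / sqrt(2), tolerance = 1e-12)
})

test_that("declared overlap widens the pooled interval", {
  est <- make_estimates(c(0.08, 0.10), c(0.02, 0.02),
                        n_case = c(10000, 10000), n_control = c(10000, 10000))
  ov <- overlap_spec("s1", "s2", n_shared_cases = 0, n_shared_controls = 5000)
  naive <- meta_fixed(est)
  adjusted <- meta_fixed(est, ov)
  expect_gt(adjusted$se, naive$se)
  # r = 0.25 for equal SEs: pooled var = s^2 (1 + r) / 2
  expect_equal(adjusted$se, 0.02 * sqrt(1.25 / 2), tolerance = 1e-10)
})

test_that("DerSimonian-Laird pooling matches hand arithmetic and a step-by-step oracle", {
  two <- make_estimates(c(0.0, 0.5), c(0.1, 0.1))
  pooled <- meta_random(two)
  expect_equal(pooled$Q, 12.5, tolerance = 1e-12)
  expect_equal(attr(pooled, "tau2"), 11.5 / 100, tolerance = 1e-12)

  # homogeneous inputs collapse to fixed effects
  hom <- make_estimates(c(0.1, 0.1, 0.1), c(0.05, 0.05, 0.05))
  expect_equal(attr(meta_random(hom), "tau2"), 0)
  expect_equal(meta_random(hom)$beta, meta_fixed(hom)$beta)
  expect_equal(meta_random(hom)$se, meta_fixed(hom)$se)

  set.seed(9)
  six <- make_estimates(rnorm(6, 0.1, 0.08), runif(6, 0.02, 0.08))
  got <- meta_random(six)
  oracle <- dl_oracle(six$beta, six$se)
  expect_equal(got$beta, oracle$beta, tolerance = 1e-12)
  expect_equal(got$se, oracle$se, tolerance = 1e-12)
  expect_equal(attr(got, "tau2"), oracle$tau2, tolerance = 1e-12)
  # random-effects SE never beats fixed-effects SE
  expect_gte(got$se, meta_fixed(six)$se)
  expect_error(meta_random(six[1, ]), class = "ratiomr_insufficient_data")
})

test_that("DerSimonian-Laird pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(10)
  est <- make_estimates(rnorm(6, 0.1, 0.1), runif(6, 0.02, 0.09))
  got <- meta_random(est)
  ref <- metafor::rma(yi = est$beta, sei = est$se, method = "DL")
  expect_equal(got$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(got$se, ref$se, tolerance = 1e-8)
  expect_equal(attr(got, "tau2"), ref$tau2, tolerance = 1e-8)
})

test_that("the Z difference test matches hand arithmetic", {
  a <- tibble::tibble(beta = 0.2, se = 0.1)
  b <- tibble::tibble(beta = 0.0, se = 0.1)
  same <- difference_test(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$pval, 1)
  d <- difference_test(a, b)
  expect_equal(d$z, sqrt(2), tolerance = 1e-12)
  expect_equal(d$pval, 2 * pnorm(-sqrt(2)), tolerance = 1e-12)
  expect_error(difference_test(a, b, covariance = 0.02),
               class = "ratiomr_validation_error")
  # a 3-group comparison via Q matches the chi-square brute force
  q3 <- cochran_q(c(0.2, 0.0, 0.1), c(0.1, 0.1, 0.1))
  w <- rep(100, 3); mu <- mean(c(0.2, 0, 0.1))
  expect_equal(q3$Q, sum(w * (c(0.2, 0, 0.1) - mu)^2), tolerance = 1e-12)
})

test_that("meta-regression recovers reductions and flags constant moderators", {
  # constant outcome: zero slope
  panel <- sim_cancer_panel(k = 8, gamma0 = 0.1, gamma1 = 0, tau2 = 0,
                            se_range = c(0.05, 0.05), seed = 1)
  est <- panel$estimates
  est$beta <- 0.1
  mr0 <- meta_regression(est, panel$covariates, "incidence")
  expect_equal(mr0$estimate[2], 0, tolerance = 1e-12)

  # binary moderator with equal SEs and tau2 = 0: difference of group means
  cov2 <- panel$covariates
  cov2$grp <- rep(c(FALSE, TRUE), 4)
  est2 <- est
  est2$beta <- ifelse(cov2$grp, 0.3, 0.1) # no residual scatter -> tau2 = 0
  mr2 <- meta_regression(est2, cov2, "grp")
  expect_equal(mr2$estimate[2], 0.2, tolerance = 1e-10)
  expect_equal(attr(mr2, "tau2"), 0)

  cov2$const <- TRUE
  expect_error(meta_regression(est2, cov2, "const"),
               class = "ratiomr_rank_error")
  expect_error(meta_regression(est2[1:3, ], cov2, "grp"),
               class = "ratiomr_insufficient_data")
})

test_that("meta-regression matches metafor's method-of-moments fit", {
  skip_if_not_installed("metafor")
  panel <- sim_cancer_panel(k = 20, gamma0 = 0.02, gamma1 = 0.05,
                            tau2 = 0.002, seed = 3)
  got <- meta_regression(panel$estimates, panel$covariates, "incidence",
                         standardize_moderator = FALSE)
  ref <- metafor::rma(yi = panel$estimates$beta, sei = panel$estimates$se,
                      mods = ~ panel$covariates$incidence, method = "DL")
  expect_equal(got$estimate, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(got$se, ref$se, tolerance = 1e-8)
  expect_equal(attr(got, "tau2"), ref$tau2, tolerance = 1e-8)
})
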