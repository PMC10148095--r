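new_mr_estimate <- function(beta, se, pval, method, n_snps,
                            Q = NA_real_, Q_df = NA_real_, Q_pval = NA_real_,
                            exposure_id = NA_character_,
                            outcome_id = NA_character_,
                            study_id = NA_character_) {
  stopifnot(se > 0)
  structure(
    tibble(exposure_id = exposure_id, outcome_id = outcome_id,
           study_id = study_id, method = method, n_snps = as.integer(n_snps),
           beta = beta, se = se, pval = pval,
           Q = Q, Q_df = Q_df, Q_pval = Q_pval),
    class = c("mr_estimate", class(tibble()))
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' The single-SNP Mendelian randomization estimator: the causal effect of
#' the exposure X on the outcome Y instrumented by SNP Z is
#' \deqn{\hat\beta_{IV} = \hat\beta_{ZY} / \hat\beta_{ZX}}
#' with standard error `se_zy / |bzx|` — the first-order approximation
#' that ignores uncertainty in the instrument-exposure association, which
#' is appropriate for a strong instrument (here, |z| of the exposure
#' association is typically far above 10). For a binary outcome with
#' `bzy` a log OR and `bzx` in exposure-SD units, `beta` is the log OR
#' per SD increase in the exposure.
#'
#' @param bzx,se_zx Instrument-exposure effect and SE (SD units).
#' @param bzy,se_zy Instrument-outcome effect and SE (log OR for binary
#'   outcomes).
#' @param exposure_id,outcome_id,study_id Optional labels.
#' @return A one-row `mr_estimate` tibble: `beta`, `se`, `pval`
#'   (two-sided normal), `method = "wald"`, `n_snps = 1`.
#' @export
wald_ratio <- function(bzx, se_zx, bzy, se_zy,
                       exposure_id = NA_character_,
                       outcome_id = NA_character_,
                       study_id = NA_character_) {
  if (bzx == 0) {
    abort("bzx = 0: Wald ratio undefined", class = "ratiomr_undefined_ratio")
  }
  beta <- bzy / bzx
  se <- se_zy / abs(bzx)
  new_mr_estimate(beta, se, z_pval(beta, se), "wald", 1L,
                  exposure_id = exposure_id, outcome_id = outcome_id,
                  study_id = study_id)
}

#' Inverse-variance weighted causal estimate from multiple instruments
#'
#' Pools per-SNP Wald ratios with inverse-variance weights
#' `w_i = bzx_i^2 / se_zy_i^2` (equivalently, weighted least squares of
#' outcome on exposure effects through the origin). Heterogeneity is
#' summarized by Cochran's Q over per-SNP ratios. The variance follows a
#' multiplicative random-effects model except with fewer than three SNPs
#' or under-dispersion: when `n >= 3` and the dispersion
#' `phi = Q/(n-1) > 1`, the fixed-effects SE is inflated by `sqrt(phi)`
#' (`method = "ivw_re"`); otherwise the fixed-effects SE is used
#' (`method = "ivw_fe"`). A single SNP falls back to [wald_ratio()].
#'
#' @param pairs Tibble of harmonized pairs (see [harmonize()]) with
#'   `exposure_beta`, `exposure_se`, `outcome_beta`, `outcome_se`; rows
#'   with `dropped_reason != "none"` are excluded. SNPs with
#'   `exposure_beta == 0` are dropped with a warning.
#' @inheritParams wald_ratio
#' @return A one-row `mr_estimate` tibble with `Q`, `Q_df`, `Q_pval`
#'   when `n_snps >= 2`.
#' @export
mr_ivw <- function(pairs, exposure_id = NA_character_,
                   outcome_id = NA_character_, study_id = NA_character_) {
  if ("dropped_reason" %in% names(pairs)) {
    pairs <- filter(pairs, .data$dropped_reason == "none")
  }
  zero <- pairs$exposure_beta == 0
  if (any(zero)) {
    warn(paste0("mr_ivw: dropping ", sum(zero), " SNP(s) with zero exposure effect"))
    pairs <- pairs[!zero, , drop = FALSE]
  }
  k <- nrow(pairs)
  if (k == 0) {
    abort("no usable SNPs for IVW estimation", class = "ratiomr_estimation_error")
  }
  if (k == 1) {
    return(wald_ratio(pairs$exposure_beta, pairs$exposure_se,
                      pairs$outcome_beta, pairs$outcome_se,
                      exposure_id = exposure_id, outcome_id = outcome_id,
                      study_id = study_id))
  }
  w <- pairs$exposure_beta^2 / pairs$outcome_se^2
  ratio <- pairs$outcome_beta / pairs$exposure_beta
  beta <- sum(pairs$exposure_beta * pairs$outcome_beta / pairs$outcome_se^2) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - beta)^2)
  Q_df <- k - 1
  phi <- Q / Q_df
  if (k >= 3 && phi > 1) {
    se <- se_fe * sqrt(phi)
    method <- "ivw_re"
  } else {
    se <- se_fe
    method <- "ivw_fe"
  }
  new_mr_estimate(beta, se, z_pval(beta, se), method, k,
                  Q = Q, Q_df = Q_df,
                  Q_pval = stats::pchisq(Q, Q_df, lower.tail = FALSE),
                  exposure_id = exposure_id, outcome_id = outcome_id,
                  study_id = study_id)
}

#' Cochran's Q test for heterogeneity
#'
#' Inverse-variance weighted heterogeneity statistic
#' `Q = sum w_i (b_i - b_pooled)^2` with `w_i = 1/se_i^2`, compared to a
#' chi-square with `k - 1` degrees of freedom. Used both across SNPs
#' within an instrument and across study- or outcome-level MR estimates.
#'
#' @param beta,se Numeric vectors of estimates and standard errors
#'   (length >= 2).
#' @return A list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  if (k < 2) abort("Cochran's Q needs at least 2 estimates",
                   class = "ratiomr_insufficient_data")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  list(Q = Q, df = k - 1,
       pval = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' Convert a log-odds-ratio estimate to an odds ratio with CI
#'
#' @param estimate An `mr_estimate` (or any tibble with `beta`, `se`).
#' @param level Confidence level (default 0.95).
#' @return The input with columns `or`, `or_lower`, `or_upper` appended.
#' @export
to_odds_ratio <- function(estimate, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  mutate(estimate,
         or = exp(.data$beta),
         or_lower = exp(.data$beta - z * .data$se),
         or_upper = exp(.data$beta + z * .data$se))
}

#' Power of a two-sample MR test for a binary outcome
#'
#' Normal approximation for the power to detect an odds ratio `or_alt` per
#' SD of exposure, with an instrument explaining `r2` of the exposure
#' variance in a case-control sample:
#' \deqn{power = \Phi(\sqrt{N r^2 \phi (1-\phi)}\,|\log or_{alt}| -
#'   z_{1-\alpha/2})}
#' where `phi` is the case fraction and `N` the total sample size.
#'
#' @param n_case,n_control Case and control counts.
#' @param r2 Instrument variance explained, in (0, 1).
#' @param or_alt Alternative-hypothesis OR per SD exposure.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power (probability of rejection).
#' @export
mr_power <- function(n_case, n_control, r2, or_alt, alpha = 0.05) {
  stopifnot(n_case > 0, n_control > 0, r2 > 0, r2 < 1, or_alt > 0, alpha > 0)
  N <- n_case + n_control
  phi <- n_case / N
  ncp <- sqrt(N * r2 * phi * (1 - phi)) * abs(log(or_alt))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2)) +
    stats::pnorm(-ncp - stats::qnorm(1 - alpha / 2))
}
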