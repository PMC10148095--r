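#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, optionally rounded to a number of significant digits for
#' presentation (e.g. 0.05/67 = 0.000746..., presented as 0.0007).
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @param digits Optional number of significant digits for presentation
#'   rounding; `NULL` (default) returns the exact threshold.
#' @return The threshold.
#' @export
bonferroni <- function(alpha, m, digits = NULL) {
  if (!is.numeric(m) || m < 1) abort("m must be >= 1",
                                     class = "ratiomr_validation_error")
  stopifnot(alpha > 0, alpha < 1)
  t <- alpha / m
  if (!is.null(digits)) t <- signif(t, digits)
  t
}

#' MR scan of one instrument across a panel of outcomes
#'
#' Estimates the instrumented exposure's effect on each outcome in a panel
#' (Wald ratio for a single SNP, IVW otherwise) and flags associations at
#' a Bonferroni-adjusted threshold `alpha/m`. Outcomes that contain none
#' of the instrument SNPs are skipped with a warning; the full table is
#' returned regardless of significance.
#'
#' @param instrument Tibble of instrument exposure records (`snp_id`,
#'   alleles, `eaf`, `beta`, `se`).
#' @param outcomes Either a named list of outcome summary-statistic tibbles
#'   or one long tibble of records for all outcomes with `trait_id`
#'   distinguishing them (as from [compute_gwas_panel()]).
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Multiplicity denominator (default the panel size).
#' @param exposure_id Optional exposure label.
#' @return A tibble of class `mr_scan`, one row per outcome, with the
#'   `mr_estimate` columns plus `alpha_adjusted` and `significant`
#'   (`pval < alpha_adjusted`), ordered as the input panel.
#' @export
trait_scan <- function(instrument, outcomes, alpha = 0.05,
                       m = NULL, exposure_id = NA_character_) {
  if (is.data.frame(outcomes)) {
    panel <- outcomes
    panel_ids <- unique(panel$trait_id)
  } else {
    panel <- purrr::list_rbind(imap(outcomes, function(o, nm) {
      mutate(o, trait_id = nm)
    }))
    panel_ids <- names(outcomes)
  }
  m <- m %||% length(panel_ids)
  if (length(panel_ids) == 0) {
    empty <- mutate(new_mr_estimate(1, 1, 1, "wald", 1L)[0, ],
                    alpha_adjusted = numeric(0), significant = logical(0))
    return(structure(empty, class = c("mr_scan", class(tibble()))))
  }
  thr <- bonferroni(alpha, m)
  pairs <- suppressMessages(harmonize(instrument, panel))
  usable <- filter(pairs, .data$dropped_reason == "none")
  missing_ids <- setdiff(panel_ids, usable$outcome_id)
  if (length(missing_ids) > 0) {
    warn(paste0("trait_scan: no usable instrument SNP for outcome(s): ",
                paste(missing_ids, collapse = ", "), "; skipped"))
  }
  counts <- table(usable$outcome_id)
  single <- names(counts)[counts == 1]
  multi <- names(counts)[counts > 1]
  res_single <- if (length(single) > 0) {
    u <- filter(usable, .data$outcome_id %in% single)
    beta <- u$outcome_beta / u$exposure_beta
    se <- u$outcome_se / abs(u$exposure_beta)
    tibble(exposure_id = exposure_id, outcome_id = u$outcome_id,
           study_id = NA_character_, method = "wald", n_snps = 1L,
           beta = beta, se = se, pval = z_pval(beta, se),
           Q = NA_real_, Q_df = NA_real_, Q_pval = NA_real_)
  }
  res_multi <- purrr::list_rbind(purrr::map(multi, function(nm) {
    mr_ivw(filter(usable, .data$outcome_id == nm),
           exposure_id = exposure_id, outcome_id = nm)
  }))
  res <- bind_rows(res_single, res_multi)
  if (nrow(res) == 0) res <- new_mr_estimate(1, 1, 1, "wald", 1L)[0, ]
  res <- res[match(intersect(panel_ids, res$outcome_id), res$outcome_id), ]
  structure(mutate(res, alpha_adjusted = thr,
                   significant = .data$pval < thr),
            class = c("mr_scan", class(tibble())))
}

#' Product-of-coefficients effect decomposition
#'
#' Decomposes a total instrumented effect on an outcome into the part
#' acting through a candidate mediator and the remainder: the indirect
#' effect is the product of the instrument-to-mediator effect `a` (per SD
#' of exposure) and the mediator-to-outcome effect `b`, with Sobel
#' standard error `sqrt(a^2 se_b^2 + b^2 se_a^2 (+ 2 a b cov_ab))`; the
#' direct effect is `total - indirect` by construction. A z test compares
#' total against indirect (treating the two as independent unless a
#' covariance is supplied), and `required_b = total/a` reports how strong
#' the mediator-outcome effect would have to be for the mediator to
#' explain the whole total effect — to be judged against what is
#' plausible for that mediator.
#'
#' @param total,se_total Total effect (log OR per SD exposure) and SE.
#' @param a,se_a Exposure-to-mediator effect (mediator SD per exposure SD)
#'   and SE.
#' @param b,se_b Mediator-to-outcome effect (log OR per mediator SD) and SE.
#' @param cov_ab Optional covariance of `a` and `b` (default 0).
#' @param cov_total_indirect Optional covariance of total and indirect
#'   estimates for the comparison test (default 0: independence).
#' @return A one-row tibble of class `mediation_result`: `total`,
#'   `indirect`, `direct` (with SEs), `prop_mediated`,
#'   `p_total_vs_indirect`, `required_b`, `required_b_lower/upper` (95%).
#' @export
decompose <- function(total, se_total, a, se_a, b, se_b,
                      cov_ab = 0, cov_total_indirect = 0) {
  stopifnot(se_total > 0, se_a > 0, se_b > 0)
  indirect <- a * b
  var_ind <- a^2 * se_b^2 + b^2 * se_a^2 + 2 * a * b * cov_ab
  if (var_ind < 0) abort("negative indirect-effect variance",
                         class = "ratiomr_validation_error")
  se_ind <- sqrt(var_ind)
  direct <- total - indirect
  v_diff <- se_total^2 + var_ind - 2 * cov_total_indirect
  se_diff <- sqrt(v_diff)
  z <- direct / se_diff
  if (a == 0) {
    warn("a = 0: required mediator effect undefined")
    rb <- rb_lo <- rb_hi <- NA_real_
  } else {
    rb <- total / a
    se_rb <- sqrt(se_total^2 / a^2 + total^2 * se_a^2 / a^4)
    zq <- stats::qnorm(0.975)
    rb_lo <- rb - zq * se_rb
    rb_hi <- rb + zq * se_rb
  }
  structure(
    tibble(total = total, se_total = se_total,
           a = a, se_a = se_a, b = b, se_b = se_b,
           indirect = indirect, se_indirect = se_ind,
           direct = direct, se_direct = sqrt(se_total^2 + var_ind),
           prop_mediated = if (total != 0) indirect / total else NA_real_,
           p_total_vs_indirect = 2 * stats::pnorm(-abs(z)),
           required_b = rb, required_b_lower = rb_lo, required_b_upper = rb_hi),
    class = c("mediation_result", class(tibble()))
  )
}

#' Phenome-wide MR scan with Bonferroni control
#'
#' Same estimation machinery as [trait_scan()] applied to a panel of
#' (typically non-neoplastic) outcomes with its own multiplicity
#' denominator, plus a directionality column for an
#' intervention-mimicking exposure: `beta_intervention = -beta` gives the
#' log OR per SD *decrease* of the exposure (P-values unchanged).
#'
#' @inheritParams trait_scan
#' @return A tibble of class `mr_scan` with the [trait_scan()] columns
#'   plus `beta_intervention` and `or_intervention`.
#' @export
phewas <- function(instrument, outcomes, alpha = 0.05,
                   m = NULL, exposure_id = NA_character_) {
  res <- trait_scan(instrument, outcomes, alpha = alpha, m = m,
                    exposure_id = exposure_id)
  structure(mutate(res, beta_intervention = -.data$beta,
                   or_intervention = exp(-.data$beta)),
            class = class(res))
}
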