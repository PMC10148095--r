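#' One replicate of the full two-study MR pipeline on synthetic data
#'
#' Exercises every stage of the summary-statistics workflow end to end:
#' simulate an exposure cohort; run component GWAS for the fatty-acid
#' pools; infer the ratio-biomarker GWAS by the delta method; select the
#' instrument by P-value threshold and LD clumping; simulate an
#' independent outcome population; sample two case-control studies with
#' shared controls; look up the instrument in each study's logistic GWAS;
#' estimate per-study causal effects by the Wald ratio; and pool them by
#' overlap-aware fixed-effects GLS.
#'
#' The generator's causal effect is set so that the estimand on the
#' measured biomarker scale — the log OR per SD of the exposure biomarker,
#' which is what the Wald ratio estimates — equals `log(or_per_sd)`
#' exactly.
#'
#' @param seed Seed for the replicate (the outcome population uses a
#'   seed offset internally so exposure and outcome samples are
#'   independent).
#' @param or_per_sd True OR per SD of the exposure biomarker.
#' @param n_exposure Exposure-cohort size (default 8631, a typical
#'   consortium GWAS of measured fatty acids).
#' @param n_population Outcome source-population size.
#' @param n_case,n_control Per-study case and control counts.
#' @param shared_controls Controls shared between the two studies.
#' @param prevalence Outcome prevalence in the source population.
#' @return A one-row tibble: instrument SNP and strength (`bzx`, `r2`),
#'   per-study estimates (`beta_a`, `beta_b`, `se_a`, `se_b`), the pooled
#'   `beta`, `se`, `pval`, the analytic shared-control correlation `r_ab`,
#'   the estimand `truth`, and `covered` (whether the pooled 95% CI
#'   contains the truth).
#' @export
pipeline_two_study <- function(seed, or_per_sd = 1.09,
                               n_exposure = 8631,
                               n_population = 60000,
                               n_case = 6000, n_control = 6000,
                               shared_controls = 3000,
                               prevalence = 0.25) {
  gamma <- 0.9
  target <- 0.87
  theta_d <- log(or_per_sd) * target / gamma
  truth <- log(or_per_sd)

  expo <- simulate_cohort(sim_config(seed = seed,
                                     n_individuals = n_exposure,
                                     theta = c(cancer = 0)))
  comp_aa <- compute_gwas(expo, "AA")
  comp_dgla <- compute_gwas(expo, "DGLA")
  ratio_gwas <- derive_ratio_gwas(comp_aa, comp_dgla, measure_moments(expo),
                                  input_scale = "sd")
  inst <- clump(ratio_gwas, make_ld_matrix(expo))

  seed_pop <- as.integer((as.numeric(seed) + 1000003) %% (2^31 - 1))
  pop <- simulate_cohort(sim_config(seed = seed_pop,
                                    n_individuals = n_population,
                                    theta = c(cancer = theta_d),
                                    prevalence = prevalence))
  sp <- split_studies(pop,
                      tibble(study_id = c("A", "B"),
                             n_case = n_case, n_control = n_control),
                      n_shared_controls = shared_controls)
  ests <- purrr::list_rbind(purrr::map(sp$studies, function(s) {
    oc <- compute_gwas(s, "cancer", "logistic", snp_ids = inst$snp_id)
    pairs <- suppressMessages(harmonize(inst, oc))
    est <- mr_ivw(pairs, exposure_id = "aadgla", outcome_id = "cancer",
                  study_id = s$study_id)
    mutate(est, n_case = sum(s$outcomes[[1]] == 1),
           n_control = sum(s$outcomes[[1]] == 0))
  }))
  pooled <- meta_fixed(ests, sp$overlap)
  zq <- stats::qnorm(0.975)
  r_ab <- overlap_correlation(ests[1, ], ests[2, ],
                              n_shared_controls = shared_controls)
  tibble(instrument = paste(inst$snp_id, collapse = "+"),
         bzx = inst$beta[1], r2 = variance_explained(inst),
         beta_a = ests$beta[1], se_a = ests$se[1],
         beta_b = ests$beta[2], se_b = ests$se[2],
         beta = pooled$beta, se = pooled$se, pval = pooled$pval,
         r_ab = r_ab, truth = truth,
         covered = abs(pooled$beta - truth) <= zq * pooled$se)
}
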