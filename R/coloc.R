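#' Wakefield approximate log Bayes factor for one SNP association
#'
#' Approximate Bayes factor comparing a normal effect prior
#' `beta ~ N(0, prior_sd^2)` against the point null, given an estimated
#' effect and standard error. With `z = beta/se` and shrinkage
#' `r = prior_sd^2 / (prior_sd^2 + se^2)`:
#' \deqn{\log ABF = 0.5 (\log(1 - r) + r z^2)}
#' (the ratio of the two marginal likelihoods of `beta_hat`).
#'
#' @param beta,se Estimated effect and standard error (`se > 0`).
#' @param prior_sd Prior SD of the true effect (> 0); conventional values
#'   are 0.15 for quantitative traits (SD units) and 0.2 for case-control
#'   traits (log-odds units).
#' @return Log Bayes factor (vectorized over inputs).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd > 0))
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Bayesian colocalisation of two traits in one region
#'
#' Enumeration-based colocalisation under the single-causal-variant
#' assumption: given per-SNP summary statistics for two traits over a
#' shared region, computes posterior probabilities of the five
#' causal-variant sharing configurations — H0 (no association), H1/H2
#' (causal variant for one trait only), H3 (two distinct causal variants)
#' and H4 (one shared causal variant). Per-SNP evidence enters through
#' Wakefield approximate Bayes factors; hypothesis sums are accumulated in
#' log space:
#' `S1 = p1 sum(A_i)`, `S2 = p2 sum(B_i)`,
#' `S3 = p1 p2 (sum(A) sum(B) - sum(A_i B_i))`, `S4 = p12 sum(A_i B_i)`,
#' `S0 = 1`, with `PP_Hk = S_k / sum(S)`.
#'
#' @param region_a,region_b Tibbles with `snp_id`, `beta`, `se` for the
#'   same region (aligned alleles); their SNP sets are intersected.
#' @param p1,p2 Per-SNP prior probabilities that a SNP is causal for trait
#'   a only / trait b only (defaults 1e-4).
#' @param p12 Per-SNP prior probability that a SNP is causal for both
#'   (default 1e-5; must not exceed `min(p1, p2)`).
#' @param trait_type_a,trait_type_b `"quant"` or `"cc"`; sets the default
#'   effect prior SD (0.15 / 0.2).
#' @param prior_sd_a,prior_sd_b Override the effect prior SDs.
#' @return A one-row tibble of class `coloc_result`: `pp_h0` ... `pp_h4`,
#'   `n_snps`, priors, and `colocalised` (`pp_h4 > 0.8`). The per-SNP log
#'   ABFs are attached as attribute `"abf"`.
#' @export
coloc_abf <- function(region_a, region_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      trait_type_a = c("quant", "cc"),
                      trait_type_b = c("quant", "cc"),
                      prior_sd_a = NULL, prior_sd_b = NULL) {
  trait_type_a <- match.arg(trait_type_a)
  trait_type_b <- match.arg(trait_type_b)
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 >= 0, p12 < 1)
  if (p12 > min(p1, p2)) {
    abort("p12 must not exceed min(p1, p2)", class = "ratiomr_validation_error")
  }
  prior_sd_a <- prior_sd_a %||% if (trait_type_a == "quant") 0.15 else 0.2
  prior_sd_b <- prior_sd_b %||% if (trait_type_b == "quant") 0.15 else 0.2
  shared <- intersect(region_a$snp_id, region_b$snp_id)
  if (length(shared) == 0) {
    abort("no shared SNPs between the two regions",
          class = "ratiomr_no_overlap")
  }
  a <- region_a[match(shared, region_a$snp_id), ]
  b <- region_b[match(shared, region_b$snp_id), ]
  la <- wakefield_log_abf(a$beta, a$se, prior_sd_a)
  lb <- wakefield_log_abf(b$beta, b$se, prior_sd_b)
  L1 <- log_sum_exp(la)           # log sum_i A_i
  L2 <- log_sum_exp(lb)           # log sum_j B_j
  L12 <- log_sum_exp(la + lb)     # log sum_i A_i B_i
  logS <- c(
    h0 = 0,
    h1 = log(p1) + L1,
    h2 = log(p2) + L2,
    h3 = log(p1) + log(p2) +
      (if (length(shared) == 1) -Inf else log_diff_exp(L1 + L2, L12)),
    h4 = if (p12 == 0) -Inf else log(p12) + L12
  )
  denom <- log_sum_exp(logS)
  pp <- exp(logS - denom)
  structure(
    tibble(pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
           pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
           n_snps = length(shared), p1 = p1, p2 = p2, p12 = p12,
           colocalised = pp[["h4"]] > 0.8),
    class = c("coloc_result", class(tibble())),
    abf = tibble(snp_id = shared, log_abf_a = la, log_abf_b = lb)
  )
}

#' Pairwise colocalisation report for several traits in one region
#'
#' Runs [coloc_abf()] for every pair of traits (e.g. cancer risk, enzyme
#' activity, and gene expression in several tissues) and assembles a tidy
#' table of posterior probabilities, one row per trait pair.
#'
#' @param regions Named list of region tibbles (`snp_id`, `beta`, `se`).
#' @param trait_types Character vector (`"quant"`/`"cc"`) per trait, same
#'   names as `regions`.
#' @param ... Passed to [coloc_abf()] (priors).
#' @return Tibble with `trait_a`, `trait_b` and the `coloc_result` columns.
#' @export
coloc_pairwise <- function(regions, trait_types = NULL, ...) {
  nms <- names(regions)
  stopifnot(length(nms) >= 2)
  trait_types <- trait_types %||% setNames(rep("quant", length(nms)), nms)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    res <- coloc_abf(regions[[p[1]]], regions[[p[2]]],
                     trait_type_a = trait_types[[p[1]]],
                     trait_type_b = trait_types[[p[2]]], ...)
    dplyr::bind_cols(tibble(trait_a = p[1], trait_b = p[2]), res)
  }) |> purrr::list_rbind()
}
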