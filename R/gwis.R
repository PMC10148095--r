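#' Phenotype moments for a ratio transform
#'
#' Container for the raw-scale moments of the numerator (`1`) and
#' denominator (`2`) phenotypes needed to infer ratio-phenotype summary
#' statistics: means, SDs, their phenotypic correlation, and the fraction
#' of samples shared between the two component GWAS (used to approximate
#' the correlation of the estimated betas).
#'
#' @param mu1,mu2 Raw-scale phenotype means; `mu2` must be bounded away
#'   from zero (at least `3 * sd2 / sqrt(n)`).
#' @param sd1,sd2 Raw-scale phenotype SDs (> 0).
#' @param rho Phenotypic correlation in \[-1, 1\].
#' @param overlap_frac Fraction of shared samples in \[0, 1\] (default 1:
#'   both phenotypes measured on the same cohort).
#' @param n Sample size used for the denominator-degeneracy check
#'   (default `Inf`, which only requires `mu2 != 0`).
#' @return A one-row tibble of class `pheno_moments`.
#' @export
pheno_moments <- function(mu1, mu2, sd1, sd2, rho, overlap_frac = 1, n = Inf) {
  stopifnot(sd1 > 0, sd2 > 0, abs(rho) <= 1,
            overlap_frac >= 0, overlap_frac <= 1)
  if (abs(mu2) <= 3 * sd2 / sqrt(n)) {
    abort("denominator mean not bounded away from 0 (|mu2| <= 3*sd2/sqrt(n))",
          class = "ratiomr_degenerate_denominator")
  }
  structure(tibble(mu1 = mu1, mu2 = mu2, sd1 = sd1, sd2 = sd2,
                   rho = rho, overlap_frac = overlap_frac, n = n),
            class = c("pheno_moments", "tbl_df", "tbl", "data.frame"))
}

#' Read / write a phenotype-moments file
#'
#' Small key-value text file with one `key<TAB>value` pair per line; keys
#' `mu1, mu2, sd1, sd2, rho, overlap_frac` (and optionally `n`).
#'
#' @param path File path.
#' @return [read_moments()] returns a `pheno_moments` object;
#'   [write_moments()] returns `path` invisibly.
#' @export
read_moments <- function(path) {
  kv <- readr::read_tsv(path, col_names = c("key", "value"),
                        show_col_types = FALSE, progress = FALSE)
  vals <- setNames(as.numeric(kv$value), kv$key)
  need <- c("mu1", "mu2", "sd1", "sd2", "rho", "overlap_frac")
  if (!all(need %in% names(vals))) {
    abort(paste0("moments file missing key(s): ",
                 paste(setdiff(need, names(vals)), collapse = ", ")),
          class = "ratiomr_format_error")
  }
  pheno_moments(vals[["mu1"]], vals[["mu2"]], vals[["sd1"]], vals[["sd2"]],
                vals[["rho"]], vals[["overlap_frac"]],
                n = if ("n" %in% names(vals)) vals[["n"]] else Inf)
}

#' @param moments A `pheno_moments` object.
#' @rdname read_moments
#' @export
write_moments <- function(moments, path) {
  m <- as.list(moments)
  keys <- c("mu1", "mu2", "sd1", "sd2", "rho", "overlap_frac", "n")
  keys <- keys[!(keys == "n" & !is.finite(m$n))]
  writeLines(paste(keys, vapply(m[keys], format, character(1), digits = 17),
                   sep = "\t"), path)
  invisible(path)
}

#' Infer ratio-phenotype GWAS summary statistics from component phenotypes
#'
#' Derives per-SNP association statistics for the ratio `X1/X2` (e.g. a
#' product-to-substrate enzyme-activity biomarker such as AA:DGLA) from the
#' component phenotypes' GWAS summary statistics, without individual-level
#' data. A first-order delta expansion about the phenotype means gives the
#' raw-scale ratio effect and its variance; the result is then standardized
#' to ratio-SD units so downstream causal estimates are "per SD increase"
#' in the biomarker:
#' \deqn{\beta_{raw} = (\beta_1 \mu_2 - \mu_1 \beta_2)/\mu_2^2}
#' \deqn{Var_{raw} = (se_1^2 \mu_2^2 + \mu_1^2 se_2^2 -
#'   2 \mu_1 \mu_2 \rho_b se_1 se_2)/\mu_2^4}
#' with \eqn{\rho_b = \rho \times overlap\_frac} the correlation of the two
#' estimated betas, and
#' \deqn{\sigma_R^2 = (\mu_1/\mu_2)^2 (sd_1^2/\mu_1^2 + sd_2^2/\mu_2^2 -
#'   2 \rho\, sd_1 sd_2/(\mu_1 \mu_2))}
#' the delta-method SD of the ratio. P-values are recomputed from
#' `beta_sd / se_sd` (two-sided normal), never carried from the inputs.
#'
#' The expansion is accurate when the denominator's coefficient of
#' variation `sd2/|mu2|` is below about 0.3; a warning is emitted above
#' that.
#'
#' @param stats_num,stats_den Summary-statistic tibbles for the numerator
#'   and denominator phenotypes, harmonized to a shared effect allele per
#'   SNP (same `effect_allele`/`other_allele` for each `snp_id`).
#' @param moments A [pheno_moments()] object for the two phenotypes.
#' @param input_scale `"raw"` if component betas are on the raw phenotype
#'   scale, `"sd"` if they are standardized (then de-standardized through
#'   the moments before the transform).
#' @param standardize If `TRUE` (default) return effects in ratio-SD units;
#'   if `FALSE` stop at the raw ratio scale (the only well-defined scale
#'   when the ratio is degenerate, e.g. identical phenotypes).
#' @return A tibble with `snp_id`, alleles and eaf carried from the inputs,
#'   `beta_raw`, `se_raw`, and (when `standardize = TRUE`) `beta_sd`,
#'   `se_sd`; `beta`/`se`/`pval` hold the output-scale values.
#' @export
derive_ratio_gwas <- function(stats_num, stats_den, moments,
                              input_scale = c("raw", "sd"),
                              standardize = TRUE) {
  input_scale <- match.arg(input_scale)
  m <- as.list(moments)
  if (abs(m$mu2) <= 3 * m$sd2 / sqrt(m$n %||% Inf)) {
    abort("degenerate denominator mean", class = "ratiomr_degenerate_denominator")
  }
  cv2 <- m$sd2 / abs(m$mu2)
  if (cv2 > 0.3) {
    warn(paste0("denominator coefficient of variation ", round(cv2, 3),
                " > 0.3: first-order delta approximation may be inaccurate"))
  }
  sr2 <- (m$mu1 / m$mu2)^2 *
    (m$sd1^2 / m$mu1^2 + m$sd2^2 / m$mu2^2 -
       2 * m$rho * m$sd1 * m$sd2 / (m$mu1 * m$mu2))
  if (standardize && (!is.finite(sr2) || sr2 <= 0)) {
    abort("delta-method ratio variance is not positive; check moments",
          class = "ratiomr_invalid_moments")
  }
  j <- inner_join(
    select(stats_num, "snp_id", "effect_allele", "other_allele",
           eaf = "eaf", b1 = "beta", s1 = "se"),
    select(stats_den, "snp_id", ea2 = "effect_allele", oa2 = "other_allele",
           b2 = "beta", s2 = "se"),
    by = "snp_id"
  )
  mismatch <- j$effect_allele != j$ea2 | j$other_allele != j$oa2
  if (any(mismatch)) {
    abort(paste0("component records not allele-consistent for: ",
                 paste(head(j$snp_id[mismatch], 5), collapse = ", ")),
          class = "ratiomr_validation_error")
  }
  if (input_scale == "sd") {
    j$b1 <- j$b1 * m$sd1; j$s1 <- j$s1 * m$sd1
    j$b2 <- j$b2 * m$sd2; j$s2 <- j$s2 * m$sd2
  }
  rho_b <- m$rho * m$overlap_frac
  beta_raw <- (j$b1 * m$mu2 - m$mu1 * j$b2) / m$mu2^2
  var_raw <- (j$s1^2 * m$mu2^2 + m$mu1^2 * j$s2^2 -
                2 * m$mu1 * m$mu2 * rho_b * j$s1 * j$s2) / m$mu2^4
  if (any(var_raw < 0)) {
    abort("negative delta-method variance; check rho/overlap_frac",
          class = "ratiomr_invalid_moments")
  }
  res <- tibble(snp_id = j$snp_id, effect_allele = j$effect_allele,
                other_allele = j$other_allele, eaf = j$eaf,
                beta_raw = beta_raw, se_raw = sqrt(var_raw))
  if (!standardize) {
    return(mutate(res, beta = beta_raw, se = .data$se_raw,
                  pval = z_pval(beta_raw, .data$se_raw)))
  }
  sigma_r <- sqrt(sr2)
  mutate(res,
         beta_sd = beta_raw / sigma_r, se_sd = .data$se_raw / sigma_r,
         beta = .data$beta_sd, se = .data$se_sd,
         pval = z_pval(.data$beta_sd, .data$se_sd))
}
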