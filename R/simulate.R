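#' Configuration for the synthetic GWAS cohort generator
#'
#' Collects every generative parameter of [simulate_cohort()]. The defaults
#' emulate the data structure the MR pipeline assumes: a single causal
#' locus with a large per-allele effect on a latent enzyme-activity trait
#' `D` (per-allele effect ~0.87 SD on the product-to-substrate biomarker,
#' explaining ~33% of its variance at eaf 0.33), positive-valued
#' (log-normal) fatty-acid pools so ratios are well defined, log-additive
#' case-control outcomes with ORs per SD in the 1.05-1.20 range, an
#' optional mediator and confounder, and optional population strata.
#'
#' @param seed Mandatory RNG seed; every source of randomness flows from it.
#' @param n_individuals Cohort size.
#' @param m_snps Number of SNPs.
#' @param ld_decay AR(1) haplotype allele correlation in \[0, 1):
#'   haplotypes are binary Markov chains with adjacent-site correlation
#'   `ld_decay` (lag-k correlation `ld_decay^k`, adjacent dosage
#'   r-squared `ld_decay^2`), clamped per SNP pair to the feasibility
#'   bound that LD imposes when allele frequencies differ.
#' @param maf_range Range of minor-allele frequencies for non-causal SNPs.
#' @param causal_index Index of the causal SNP (default: middle).
#' @param causal_maf Effect-allele frequency of the causal SNP.
#' @param gamma Per-allele SD effect of the causal SNP on latent activity
#'   `D` (population SD of `D` is 1 by construction).
#' @param ratio_targets Named vector of target per-allele SD effects on the
#'   two biomarker ratios `AA:DGLA` and `GLA:LA`; biomarker noise is solved
#'   so the standardized-ratio effect matches the target given `gamma`.
#' @param ratio_slopes Named vector of log-scale ratio loadings on `D`
#'   (how steeply each ratio responds to activity).
#' @param theta Named vector: true log OR per SD of `D` for each binary
#'   outcome (or slope per SD for quantitative outcomes).
#' @param prevalence Baseline outcome prevalence (binary outcomes).
#' @param outcome_type `"binary"` or `"quantitative"`.
#' @param mediator List `(a, b)`: `a` = mediator SD per SD of `D`; `b` =
#'   mediator effect on each outcome (log OR or slope per mediator SD).
#'   With a mediator, `theta` is the *direct* effect and the total effect
#'   is `theta + a * b`.
#' @param confounder List `(on_exposure, on_outcome)`: effects of a
#'   standard-normal confounder `U` on `D` and on the outcome linear
#'   predictor.
#' @param poly_sd_components Per-SNP SD of polygenic effects of non-causal
#'   SNPs on the log fatty-acid pools (0 = monogenic biomarkers).
#' @param strata Optional list for a two-subpopulation stratification
#'   scenario: `prop` (fraction in stratum 2), `maf_shift` (added to all
#'   MAFs in stratum 2, clamped to (0.01, 0.99)), `risk_shift` (added to
#'   the outcome linear predictor in stratum 2), `pheno_shift` (added to
#'   `D` in stratum 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_individuals = 20000,
                       m_snps = 20,
                       ld_decay = 0.8,
                       maf_range = c(0.05, 0.5),
                       causal_index = NULL,
                       causal_maf = 0.33,
                       gamma = 0.9,
                       ratio_targets = c(aadgla = 0.87, glala = 0.38),
                       ratio_slopes = c(aadgla = 0.2, glala = 0.0874),
                       theta = c(cancer = log(1.09)),
                       prevalence = 0.10,
                       outcome_type = c("binary", "quantitative"),
                       mediator = list(a = 0, b = 0),
                       confounder = list(on_exposure = 0, on_outcome = 0),
                       poly_sd_components = 0,
                       strata = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) abort("seed is mandatory", class = "ratiomr_config_error")
  stopifnot(n_individuals > 1, m_snps >= 1,
            ld_decay >= 0, ld_decay < 1,
            causal_maf > 0, causal_maf < 1,
            prevalence > 0, prevalence < 1)
  causal_index <- causal_index %||% ceiling(m_snps / 2)
  if (causal_index < 1 || causal_index > m_snps) {
    abort("causal_index out of range", class = "ratiomr_config_error")
  }
  if (abs(gamma) > 0 && gamma^2 * 2 * causal_maf * (1 - causal_maf) > 1) {
    abort("gamma too large: causal SNP would explain > 100% of D's variance",
          class = "ratiomr_config_error")
  }
  structure(list(seed = seed, n_individuals = n_individuals, m_snps = m_snps,
                 ld_decay = ld_decay, maf_range = maf_range,
                 causal_index = causal_index, causal_maf = causal_maf,
                 gamma = gamma, ratio_targets = ratio_targets,
                 ratio_slopes = ratio_slopes, theta = theta,
                 prevalence = prevalence, outcome_type = outcome_type,
                 mediator = mediator, confounder = confounder,
                 poly_sd_components = poly_sd_components, strata = strata),
            class = "sim_config")
}

# biomarker log-scale noise SD giving a standardized-ratio per-allele
# effect of `target` when activity has per-allele effect `gamma` and the
# log ratio responds to activity with slope `slope`
solve_ratio_noise <- function(gamma, target, slope) {
  # no genetic signal: target is moot, keep a moderate biomarker noise
  if (gamma == 0) return(slope * 0.3)
  if (target >= abs(gamma)) {
    abort("ratio target effect cannot exceed gamma",
          class = "ratiomr_config_error")
  }
  slope * sqrt((gamma / target)^2 - 1)
}

# AR(1) Markov-chain haplotypes -> dosage matrix (n x m).
# Adjacent alleles have correlation ld_decay (so lag-k correlation
# ld_decay^k and adjacent dosage r2 = ld_decay^2), clamped per pair to the
# feasibility bound LD imposes when allele frequencies differ.
draw_genotypes <- function(n, maf, ld_decay) {
  m <- length(maf)
  if (m == 1) {
    return(matrix(stats::rbinom(n, 2, maf), ncol = 1,
                  dimnames = list(NULL, NULL)))
  }
  hap <- function() {
    if (ld_decay == 0) {
      return(matrix(stats::rbinom(n * m, 1, rep(maf, each = n)), n, m))
    }
    H <- matrix(0L, n, m)
    H[, 1] <- stats::rbinom(n, 1, maf[1])
    for (j in 2:m) {
      p1 <- maf[j - 1]; p2 <- maf[j]
      k <- sqrt(p2 * (1 - p2) / (p1 * (1 - p1)))
      rmax <- min(p2 / (p1 * k), (1 - p2) / ((1 - p1) * k))
      r <- min(ld_decay, rmax)
      p <- p2 + r * k * (H[, j - 1] - p1)
      H[, j] <- stats::rbinom(n, 1, pmin(pmax(p, 0), 1))
    }
    H
  }
  hap() + hap()
}

#' Simulate a cohort with known ground truth
#'
#' Generates genotypes (AR(1) binary Markov-chain haplotypes), a latent
#' enzyme-activity trait `D` (unit variance) driven by one causal SNP,
#' log-normal fatty-acid pools `AA`, `DGLA`, `GLA`, `LA` whose
#' product-to-substrate ratios are biomarkers of `D`, an optional mediator
#' and confounder, and one column per outcome (binary via a log-additive
#' logistic model, or quantitative). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study`: `genotypes` (n x m dosage
#'   matrix), `snps` (tibble: `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `maf`), `phenotypes` (tibble with `D`, the pools, the
#'   ratios `aadgla`/`glala`, `mediator`, `confounder`, `stratum`),
#'   `outcomes` (tibble, one column per name in `config$theta`),
#'   `ground_truth` (list of every generative parameter plus derived
#'   estimands), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$m_snps
  cidx <- config$causal_index

  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  maf[cidx] <- config$causal_maf

  # strata: subpopulation labels, allele-frequency and baseline offsets
  if (!is.null(config$strata)) {
    s2 <- stats::rbinom(n, 1, config$strata$prop)
  } else {
    s2 <- rep(0L, n)
  }
  if (!is.null(config$strata) && any(s2 == 1)) {
    maf2 <- pmin(pmax(maf + config$strata$maf_shift, 0.01), 0.99)
    G <- matrix(0L, n, m)
    G[s2 == 0, ] <- draw_genotypes(sum(s2 == 0), maf, config$ld_decay)
    G[s2 == 1, ] <- draw_genotypes(sum(s2 == 1), maf2, config$ld_decay)
  } else {
    G <- draw_genotypes(n, maf, config$ld_decay)
  }
  alleles <- tibble(
    snp_id = sprintf("rs%04d", seq_len(m)),
    chrom = "11",
    pos = as.integer(61500000 + seq_len(m) * 5000),
    effect_allele = rep(c("C", "A", "G", "T"), length.out = m),
    other_allele = rep(c("T", "G", "A", "C"), length.out = m),
    maf = maf
  )
  colnames(G) <- alleles$snp_id

  # latent activity D: unit population variance, causal SNP explains
  # gamma^2 * 2f(1-f)
  gc <- G[, cidx] - 2 * config$causal_maf
  U <- rnorm(n)
  var_from_snp <- config$gamma^2 * 2 * config$causal_maf * (1 - config$causal_maf)
  var_from_conf <- config$confounder$on_exposure^2
  noise_var <- max(0, 1 - var_from_snp - var_from_conf)
  D <- config$gamma * gc + config$confounder$on_exposure * U +
    rnorm(n, 0, sqrt(noise_var))
  if (!is.null(config$strata)) D <- D + config$strata$pheno_shift * s2

  # polygenic secondary effects of non-causal SNPs on the log pools
  poly <- function() {
    if (config$poly_sd_components <= 0) return(list(b = numeric(m), x = 0))
    b <- rnorm(m, 0, config$poly_sd_components)
    b[cidx] <- 0
    list(b = b, x = drop(sweep(G, 2, 2 * maf) %*% b))
  }
  sig1 <- solve_ratio_noise(config$gamma, config$ratio_targets[["aadgla"]],
                            config$ratio_slopes[["aadgla"]])
  sig2 <- solve_ratio_noise(config$gamma, config$ratio_targets[["glala"]],
                            config$ratio_slopes[["glala"]])
  p_aa <- poly(); p_dgla <- poly(); p_gla <- poly(); p_la <- poly()
  s1h <- config$ratio_slopes[["aadgla"]] / 2
  s2h <- config$ratio_slopes[["glala"]] / 2
  AA   <- exp(log(5) + s1h * D + p_aa$x   + rnorm(n, 0, sig1 / sqrt(2)))
  DGLA <- exp(log(2) - s1h * D + p_dgla$x + rnorm(n, 0, sig1 / sqrt(2)))
  GLA  <- exp(log(0.5) + s2h * D + p_gla$x + rnorm(n, 0, sig2 / sqrt(2)))
  LA   <- exp(log(20) - s2h * D + p_la$x  + rnorm(n, 0, sig2 / sqrt(2)))

  med_a <- config$mediator$a
  M <- med_a * D + rnorm(n, 0, sqrt(max(0, 1 - med_a^2)))

  outc <- purrr::imap(as.list(config$theta), function(th, nm) {
    lp <- th * D + config$mediator$b * M + config$confounder$on_outcome * U
    if (!is.null(config$strata)) lp <- lp + config$strata$risk_shift * s2
    if (config$outcome_type == "binary") {
      alpha <- stats::qlogis(config$prevalence)
      stats::rbinom(n, 1, stats::plogis(alpha + lp))
    } else {
      lp + rnorm(n)
    }
  })
  outcomes <- as_tibble(outc)

  ground_truth <- list(
    gamma = config$gamma, causal_snp = alleles$snp_id[cidx],
    causal_index = cidx, causal_maf = config$causal_maf,
    variance_explained_D = var_from_snp,
    ratio_targets = config$ratio_targets,
    ratio_noise_sd = c(aadgla = sig1, glala = sig2),
    theta = config$theta,
    mediator = config$mediator,
    total_effect = config$theta + med_a * config$mediator$b,
    prop_mediated = ifelse(config$theta + med_a * config$mediator$b != 0,
                           med_a * config$mediator$b /
                             (config$theta + med_a * config$mediator$b), NA),
    confounder = config$confounder,
    poly_betas = list(aa = p_aa$b, dgla = p_dgla$b, gla = p_gla$b, la = p_la$b)
  )
  structure(list(
    genotypes = G,
    snps = alleles,
    phenotypes = tibble(D = D, AA = AA, DGLA = DGLA, GLA = GLA, LA = LA,
                        aadgla = AA / DGLA, glala = GLA / LA,
                        mediator = M, confounder = U, stratum = s2),
    outcomes = outcomes,
    ground_truth = ground_truth,
    config = config
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> n =", nrow(x$genotypes),
      "| SNPs =", ncol(x$genotypes),
      "| outcomes:", paste(names(x$outcomes), collapse = ", "),
      "| causal:", x$ground_truth$causal_snp, "\n")
  invisible(x)
}

# single-SNP logistic Wald fit; returns c(beta, se)
fast_logistic <- function(g, y) {
  X <- cbind(1, g)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  w <- fit$weights
  V <- solve(crossprod(X * sqrt(w)))
  c(unname(fit$coefficients[2]), sqrt(V[2, 2]))
}

# Newton-Raphson logistic regression of many binary outcomes on one shared
# dosage vector; exact MLE per outcome, vectorized across outcomes.
# Returns list(beta, se) of length ncol(Y).
batch_logistic <- function(g, Y, max_iter = 30, tol = 1e-10) {
  Y <- as.matrix(Y)
  n <- length(g); k <- ncol(Y)
  a <- stats::qlogis(pmin(pmax(colMeans(Y), 1e-8), 1 - 1e-8))
  b <- numeric(k)
  S0 <- S1 <- S2 <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- tcrossprod(g, b) + matrix(a, n, k, byrow = TRUE)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- Y - mu
    U0 <- colSums(r); U1 <- colSums(r * g)
    S0 <- colSums(w); S1 <- colSums(w * g); S2 <- colSums(w * g^2)
    det <- S0 * S2 - S1^2
    da <- (S2 * U0 - S1 * U1) / det
    db <- (S0 * U1 - S1 * U0) / det
    a <- a + da; b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  list(beta = unname(b), se = unname(sqrt(S0 / (S0 * S2 - S1^2))))
}

#' Per-SNP GWAS on a simulated cohort
#'
#' Univariate regression of a trait on allele dosage for each SNP.
#' Quantitative traits are standardized to SD units first (linear model,
#' closed form); binary traits use logistic regression (per-allele log
#' odds). Emits records in the standard summary-statistic dialect with the
#' generator's alleles and observed eafs. Monomorphic SNPs are emitted
#' with `beta = 0`, missing `se`, and flagged in the `note` column.
#'
#' @param study A [simulate_cohort()] result (or a sub-study from
#'   [split_studies()]).
#' @param trait Name of a phenotype or outcome column.
#' @param model `"linear"` or `"logistic"`.
#' @param snp_ids Optional subset of SNPs (e.g. just the instrument, as in
#'   an outcome-GWAS lookup).
#' @return Tibble of summary-statistic records (see [read_sumstats()]).
#' @export
compute_gwas <- function(study, trait, model = c("linear", "logistic"),
                         snp_ids = NULL) {
  model <- match.arg(model)
  y <- study$phenotypes[[trait]] %||% study$outcomes[[trait]]
  if (is.null(y)) abort(paste0("unknown trait: ", trait),
                        class = "ratiomr_config_error")
  G <- study$genotypes
  if (!is.null(snp_ids)) G <- G[, snp_ids, drop = FALSE]
  n <- length(y)
  mono <- unname(apply(G, 2, function(g) var(g) == 0))
  if (model == "logistic") {
    if (length(unique(y)) < 2) abort("logistic model needs both classes",
                                     class = "ratiomr_config_error")
    est <- vapply(seq_len(ncol(G)), function(j) {
      if (mono[j]) return(c(0, NA_real_))
      fast_logistic(G[, j], y)
    }, numeric(2))
    beta <- est[1, ]; se <- est[2, ]
    pval <- z_pval(beta, se)
    n_case <- sum(y == 1); n_control <- sum(y == 0)
  } else {
    ys <- (y - mean(y)) / sd(y)
    gm <- colMeans(G)
    gcn <- sweep(G, 2, gm)
    sxx <- unname(colSums(gcn^2))
    sxy <- unname(colSums(gcn * ys))
    beta <- ifelse(sxx > 0, sxy / sxx, 0)
    syy <- sum(ys^2)
    sigma2 <- pmax(0, (syy - beta^2 * sxx) / (n - 2))
    se <- ifelse(sxx > 0, sqrt(sigma2 / sxx), NA_real_)
    tstat <- beta / se
    pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
    n_case <- NA_integer_; n_control <- NA_integer_
  }
  snps <- study$snps[match(colnames(G), study$snps$snp_id), ]
  tibble(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
         effect_allele = snps$effect_allele, other_allele = snps$other_allele,
         eaf = unname(colMeans(G)) / 2,
         beta = beta, se = se,
         pval = ifelse(mono, NA_real_, pval),
         n = n, n_case = n_case, n_control = n_control,
         trait_id = trait, ancestry = "SIM",
         note = ifelse(mono, "monomorphic", NA_character_))
}

#' Single-SNP GWAS lookups for a panel of binary outcomes
#'
#' Logistic per-allele association of each outcome in a panel with one SNP
#' (typically the instrument), fitted by Newton-Raphson jointly across
#' outcomes — the fast path for phenome-wide scans over many outcomes.
#' Identical estimates to [compute_gwas()] with `model = "logistic"`.
#'
#' @param study A `synthetic_study` whose `outcomes` are binary.
#' @param traits Outcome column names (default: all).
#' @param snp_id SNP to test (default: the causal SNP).
#' @return A long tibble of summary-statistic records, one row per
#'   outcome, `trait_id` identifying the outcome.
#' @export
compute_gwas_panel <- function(study, traits = names(study$outcomes),
                               snp_id = study$ground_truth$causal_snp) {
  g <- study$genotypes[, snp_id]
  Y <- as.matrix(study$outcomes[, traits, drop = FALSE])
  fit <- batch_logistic(g, Y)
  snp <- study$snps[match(snp_id, study$snps$snp_id), ]
  tibble(snp_id = snp_id, chrom = snp$chrom, pos = snp$pos,
         effect_allele = snp$effect_allele, other_allele = snp$other_allele,
         eaf = mean(g) / 2,
         beta = fit$beta, se = fit$se, pval = z_pval(fit$beta, fit$se),
         n = length(g), n_case = unname(colSums(Y)),
         n_control = length(g) - unname(colSums(Y)),
         trait_id = traits, ancestry = "SIM")
}

#' Empirical LD matrix of a simulated cohort
#'
#' Squared Pearson correlation of allele dosages; symmetric with unit
#' diagonal. Monomorphic SNPs get zero off-diagonal r-squared (with a
#' warning) and keep a diagonal of 1.
#'
#' @param study A `synthetic_study`.
#' @return Square r-squared matrix with SNP-ID dimnames.
#' @export
make_ld_matrix <- function(study) {
  G <- study$genotypes
  stopifnot(ncol(G) >= 2)
  v <- apply(G, 2, var)
  r2 <- suppressWarnings(cor(G))^2
  if (any(v == 0)) {
    warn(paste0("make_ld_matrix: ", sum(v == 0),
                " monomorphic SNP(s); r2 set to 0"))
    r2[v == 0, ] <- 0
    r2[, v == 0] <- 0
  }
  diag(r2) <- 1
  dimnames(r2) <- list(colnames(G), colnames(G))
  r2
}

#' Measure ratio-transform moments from a simulated cohort
#'
#' @param study A `synthetic_study`.
#' @param num,den Phenotype column names of numerator and denominator.
#' @return A [pheno_moments()] with `rho` the observed phenotypic
#'   correlation and `overlap_frac = 1` (both measured on one cohort).
#' @export
measure_moments <- function(study, num = "AA", den = "DGLA") {
  x1 <- study$phenotypes[[num]]
  x2 <- study$phenotypes[[den]]
  pheno_moments(mean(x1), mean(x2), sd(x1), sd(x2), cor(x1, x2),
                overlap_frac = 1, n = length(x1))
}

subset_study <- function(study, idx, outcome, study_id) {
  ph <- study$phenotypes[idx, ]
  structure(list(
    genotypes = study$genotypes[idx, , drop = FALSE],
    snps = study$snps,
    phenotypes = ph,
    outcomes = study$outcomes[idx, outcome, drop = FALSE],
    ground_truth = study$ground_truth,
    config = study$config,
    study_id = study_id,
    indices = idx
  ), class = "synthetic_study")
}

#' Split a simulated population into case-control studies with shared controls
#'
#' Retrospective sampling: cases and controls for each sub-study are drawn
#' from the population's case and control pools. Cases are always
#' disjoint between studies; the requested number of shared controls (and
#' optionally shared cases) is realized exactly for two studies, and the
#' emitted [overlap_spec()] records the realized sharing.
#'
#' @param study A `synthetic_study` with a binary outcome.
#' @param split_spec Tibble with columns `study_id`, `n_case`, `n_control`
#'   (one row per sub-study), plus attributes via arguments below.
#' @param n_shared_controls,n_shared_cases Shared counts between the two
#'   studies (only supported for exactly two studies; default 0).
#' @param outcome Outcome column to sample on (default: first).
#' @return A list with `studies` (list of `synthetic_study`) and `overlap`
#'   (an [overlap_spec()] matching the realized sharing exactly).
#' @export
split_studies <- function(study, split_spec, n_shared_controls = 0,
                          n_shared_cases = 0,
                          outcome = names(study$outcomes)[1]) {
  y <- study$outcomes[[outcome]]
  cases <- which(y == 1); controls <- which(y == 0)
  k <- nrow(split_spec)
  if (k > 2 && (n_shared_controls > 0 || n_shared_cases > 0)) {
    abort("shared subjects supported for exactly two studies",
          class = "ratiomr_config_error")
  }
  need_cases <- sum(split_spec$n_case) - n_shared_cases
  need_controls <- sum(split_spec$n_control) - n_shared_controls
  if (need_cases > length(cases) || need_controls > length(controls)) {
    abort("infeasible split: population has too few cases or controls",
          class = "ratiomr_config_error")
  }
  take <- function(pool, n) pool[seq_len(n)]
  studies <- vector("list", k)
  if (k == 2 && (n_shared_controls > 0 || n_shared_cases > 0)) {
    sh_co <- take(controls, n_shared_controls)
    controls_rest <- setdiff(controls, sh_co)
    sh_ca <- take(cases, n_shared_cases)
    cases_rest <- setdiff(cases, sh_ca)
    ca1 <- take(cases_rest, split_spec$n_case[1] - n_shared_cases)
    ca2 <- take(setdiff(cases_rest, ca1), split_spec$n_case[2] - n_shared_cases)
    co1 <- take(controls_rest, split_spec$n_control[1] - n_shared_controls)
    co2 <- take(setdiff(controls_rest, co1),
                split_spec$n_control[2] - n_shared_controls)
    studies[[1]] <- subset_study(study, c(sh_ca, ca1, sh_co, co1), outcome,
                                 split_spec$study_id[1])
    studies[[2]] <- subset_study(study, c(sh_ca, ca2, sh_co, co2), outcome,
                                 split_spec$study_id[2])
  } else {
    ca_pool <- cases; co_pool <- controls
    for (i in seq_len(k)) {
      ca <- take(ca_pool, split_spec$n_case[i])
      co <- take(co_pool, split_spec$n_control[i])
      ca_pool <- setdiff(ca_pool, ca); co_pool <- setdiff(co_pool, co)
      studies[[i]] <- subset_study(study, c(ca, co), outcome,
                                   split_spec$study_id[i])
    }
  }
  ov <- if (k == 2) {
    overlap_spec(split_spec$study_id[1], split_spec$study_id[2],
                 n_shared_cases, n_shared_controls)
  } else {
    pairs <- utils::combn(split_spec$study_id, 2)
    overlap_spec(pairs[1, ], pairs[2, ],
                 rep(0L, ncol(pairs)), rep(0L, ncol(pairs)))
  }
  list(studies = studies, overlap = ov)
}

#' Scenario presets for the synthetic-data generator
#'
#' Named configurations covering the situations the pipeline must handle:
#' \describe{
#'   \item{null}{valid strong instrument, no causal effect on the outcome
#'     (`theta = 0`) — calibration of the Wald test.}
#'   \item{causal}{OR per SD = 1.09 on one cancer.}
#'   \item{gwis}{60 independent SNPs with polygenic effects on the
#'     fatty-acid pools — validation of the inferred ratio GWAS against
#'     individual-level regression.}
#'   \item{mediated}{quantitative outcome with a mediator carrying 40% of
#'     the total effect (`a = 0.6`, `b = 0.4`, direct 0.36).}
#'   \item{confounded}{a confounder affecting both activity and outcome,
#'     no causal effect.}
#'   \item{stratified}{two subpopulations differing in allele frequency,
#'     baseline risk and biomarker mean; no genetic effect anywhere —
#'     population stratification induces a spurious association.}
#'   \item{overlapping}{large population intended for
#'     [split_studies()] into two case-control studies with shared
#'     controls; OR per SD = 1.09.}
#' }
#'
#' @param name Preset name.
#' @param seed RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_scenario <- function(name = c("null", "causal", "gwis", "mediated",
                                  "confounded", "stratified", "overlapping"),
                         seed, ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    null = list(theta = c(cancer = 0)),
    causal = list(theta = c(cancer = log(1.09))),
    gwis = list(m_snps = 60, ld_decay = 0, poly_sd_components = 0.02,
                theta = c(cancer = 0)),
    mediated = list(outcome_type = "quantitative",
                    theta = c(outcome = 0.36),
                    mediator = list(a = 0.6, b = 0.4)),
    confounded = list(theta = c(cancer = 0),
                      confounder = list(on_exposure = 0.3, on_outcome = 0.4)),
    stratified = list(gamma = 0, theta = c(cancer = 0), ld_decay = 0,
                      strata = list(prop = 0.5, maf_shift = 0.3,
                                    risk_shift = 1.0, pheno_shift = 1.0)),
    overlapping = list(n_individuals = 60000, prevalence = 0.25,
                       theta = c(cancer = log(1.09)))
  )
  args <- utils::modifyList(c(list(seed = seed), base), list(...))
  do.call(sim_config, args)
}

#' Simulate an outcome-level panel for meta-regression
#'
#' Generates `k` synthetic cancers with a covariate table and per-cancer
#' MR estimates following the meta-regression model
#' `beta_c = gamma0 + gamma1 x_c + u_c + e_c`, `u_c ~ N(0, tau2)`,
#' `e_c ~ N(0, se_c^2)`, with the moderator standardized.
#'
#' @param k Number of cancers.
#' @param gamma0,gamma1 Intercept and moderator slope.
#' @param tau2 Residual between-cancer variance.
#' @param se_range Range of per-cancer standard errors.
#' @param seed RNG seed.
#' @return List with `estimates` (tibble of `mr_estimate` rows) and
#'   `covariates` (tibble keyed by `cancer_id` with moderator `incidence`
#'   standardized and other plausible covariate columns).
#' @export
sim_cancer_panel <- function(k = 40, gamma0 = 0.02, gamma1 = 0.05,
                             tau2 = 0.001, se_range = c(0.02, 0.08), seed) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(k)))
  se <- runif(k, se_range[1], se_range[2])
  beta <- gamma0 + gamma1 * x + rnorm(k, 0, sqrt(tau2)) + rnorm(k, 0, se)
  ids <- sprintf("cancer%02d", seq_len(k))
  estimates <- purrr::list_rbind(purrr::map(seq_len(k), function(i) {
    new_mr_estimate(beta[i], se[i], z_pval(beta[i], se[i]), "wald", 1L,
                    exposure_id = "activity", outcome_id = ids[i],
                    study_id = ids[i])
  }))
  covariates <- tibble(
    cancer_id = ids,
    incidence = x,
    smoking_related = rbinom(k, 1, 0.4) == 1,
    inflammation_related = rbinom(k, 1, 0.3) == 1,
    survival_time = runif(k, 1, 15),
    median_age_dx = runif(k, 45, 75),
    stem_cell_divisions = rnorm(k),
    system = sample(c("reproductive", "urinary", "nervous", "blood",
                      "digestive", "respiratory", "skin", "other"),
                    k, replace = TRUE)
  )
  list(estimates = estimates, covariates = covariates)
}

#' Write a simulated study's analysis inputs to a directory
#'
#' Emits the text files the pipeline consumes: per-trait summary-statistic
#' TSVs, the LD matrix, the ratio moments file, and a plain-text
#' ground-truth manifest.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @param traits Phenotype names to run linear GWAS on.
#' @param outcomes Outcome names to run logistic GWAS on (binary cohorts).
#' @return `dir`, invisibly.
#' @export
export_study <- function(study, dir, traits = c("aadgla"),
                         outcomes = names(study$outcomes)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in traits) {
    write_sumstats(compute_gwas(study, tr, "linear"),
                   file.path(dir, paste0(tr, ".tsv")))
  }
  if (study$config$outcome_type == "binary") {
    for (oc in outcomes) {
      write_sumstats(compute_gwas(study, oc, "logistic"),
                     file.path(dir, paste0(oc, ".tsv")))
    }
  }
  write_ld_matrix(make_ld_matrix(study), file.path(dir, "ld.tsv"))
  write_moments(measure_moments(study), file.path(dir, "moments.tsv"))
  gt <- study$ground_truth
  gt$poly_betas <- NULL
  writeLines(paste(names(unlist(gt)), unlist(gt), sep = "\t"),
             file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
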