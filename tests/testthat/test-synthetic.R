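test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- sim_scenario("causal", seed = 71, n_individuals = 500, m_snps = 6)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$outcomes, s2$outcomes)
})

test_that("GWAS P-values are uniform under the global null", {
  cfg <- sim_config(seed = 72, n_individuals = 2000, m_snps = 5000,
                    ld_decay = 0, gamma = 0, theta = c(cancer = 0))
  st <- simulate_cohort(cfg)
  gw <- compute_gwas(st, "D", "linear")
  ks <- suppressWarnings(ks.test(gw$pval, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the causal SNP carries the strongest signal and the stated variance explained", {
  st <- simulate_cohort(sim_scenario("causal", seed = 73))
  gw <- compute_gwas(st, "aadgla", "linear")
  # P-values underflow at this signal strength; rank by |z|
  expect_equal(which.max(abs(gw$beta / gw$se)),
               st$ground_truth$causal_index)
  # per-allele effect on the standardized ratio near the configured target
  b_hat <- gw$beta[st$ground_truth$causal_index]
  expect_lt(abs(b_hat - 0.87), 0.05)
  inst <- gw[st$ground_truth$causal_index, ]
  expect_lt(abs(variance_explained(inst) - 0.33), 0.03)
})

test_that("logistic GWAS recovers the generative log OR at the causal SNP", {
  cfg <- sim_scenario("causal", seed = 74, n_individuals = 40000,
                      theta = c(cancer = log(1.5)), prevalence = 0.2)
  st <- simulate_cohort(cfg)
  gw <- compute_gwas(st, "cancer", "logistic",
                     snp_ids = st$ground_truth$causal_snp)
  # log-additive model: per-allele log OR ~= theta * gamma
  expect_lt(abs(gw$beta - log(1.5) * 0.9), 4 * gw$se)
  # the batched panel fit matches the per-outcome fit
  pn <- compute_gwas_panel(st)
  expect_equal(pn$beta, gw$beta, tolerance = 1e-6)
  expect_equal(pn$se, gw$se, tolerance = 1e-6)
})

test_that("AR(1) haplotypes give the closed-form adjacent dosage r-squared", {
  cfg <- sim_config(seed = 75, n_individuals = 20000, m_snps = 10,
                    ld_decay = 0.9, maf_range = c(0.3, 0.3),
                    causal_maf = 0.3)
  st <- simulate_cohort(cfg)
  ld <- make_ld_matrix(st)
  adj <- ld[cbind(1:9, 2:10)]
  expect_equal(mean(adj), 0.81, tolerance = 0.02)
  lag2 <- ld[cbind(1:8, 3:10)]
  expect_equal(mean(lag2), 0.9^4, tolerance = 0.03)
  # independent SNPs: negligible off-diagonal LD
  st0 <- simulate_cohort(sim_config(seed = 76, n_individuals = 20000,
                                    m_snps = 10, ld_decay = 0))
  ld0 <- make_ld_matrix(st0)
  expect_lt(max(ld0[upper.tri(ld0)]), 0.01)
  expect_equal(diag(ld0), setNames(rep(1, 10), colnames(ld0)))
})

test_that("LD matrix files round-trip and are validated", {
  st <- simulate_cohort(sim_config(seed = 77, n_individuals = 500, m_snps = 4))
  ld <- make_ld_matrix(st)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  ld2 <- read_ld_matrix(path)
  expect_equal(ld2, ld, tolerance = 1e-12)
  bad <- ld; bad[1, 2] <- 1.5
  expect_error(ratiomr:::validate_ld_matrix(bad),
               class = "ratiomr_validation_error")
})

test_that("study splits realize the requested sharing exactly", {
  st <- simulate_cohort(sim_scenario("overlapping", seed = 78,
                                     n_individuals = 30000))
  spec2 <- tibble::tibble(study_id = c("A", "B"),
                          n_case = c(3000, 3000), n_control = c(3000, 3000))
  sp <- split_studies(st, spec2, n_shared_controls = 1500)
  expect_equal(length(intersect(sp$studies[[1]]$indices,
                                sp$studies[[2]]$indices)), 1500)
  expect_equal(sp$overlap$n_shared_controls, 1500L)
  expect_equal(sum(sp$studies[[1]]$outcomes[[1]]), 3000)
  # no sharing
  sp0 <- split_studies(st, spec2)
  expect_equal(length(intersect(sp0$studies[[1]]$indices,
                                sp0$studies[[2]]$indices)), 0)
  expect_equal(sp0$overlap$n_shared_controls, 0L)
  # infeasible request
  spec_big <- tibble::tibble(study_id = c("A", "B"),
                             n_case = c(2e5, 2e5), n_control = c(100, 100))
  expect_error(split_studies(st, spec_big), class = "ratiomr_config_error")
})

test_that("population stratification induces a spurious effect that stratification removes", {
  st <- simulate_cohort(sim_scenario("stratified", seed = 79,
                                     n_individuals = 20000))
  snp <- st$snps$snp_id[st$ground_truth$causal_index]
  # pooled analysis: allele frequency + baseline risk differences create
  # a spurious instrument-outcome association
  pooled <- compute_gwas(st, "cancer", "logistic", snp_ids = snp)
  expect_lt(pooled$pval, 1e-4)
  # within each stratum the association vanishes
  z_within <- sapply(0:1, function(s) {
    idx <- which(st$phenotypes$stratum == s)
    sub <- ratiomr:::subset_study(st, idx, "cancer", paste0("str", s))
    gw <- compute_gwas(sub, "cancer", "logistic", snp_ids = snp)
    abs(gw$beta / gw$se)
  })
  expect_true(all(z_within < 3))
})

test_that("exported study files can be read back by the pipeline readers", {
  st <- simulate_cohort(sim_scenario("causal", seed = 80,
                                     n_individuals = 1000, m_snps = 4))
  dir <- withr::local_tempdir()
  export_study(st, dir)
  ss <- read_sumstats(file.path(dir, "aadgla.tsv"))
  expect_equal(nrow(ss), 4)
  ld <- read_ld_matrix(file.path(dir, "ld.tsv"))
  expect_equal(dim(ld), c(4, 4))
  mom <- read_moments(file.path(dir, "moments.tsv"))
  expect_s3_class(mom, "pheno_moments")
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
})

test_that("monomorphic SNPs are flagged in GWAS output and zeroed in LD", {
  st <- simulate_cohort(sim_config(seed = 81, n_individuals = 300,
                                   m_snps = 3, ld_decay = 0))
  st$genotypes[, 2] <- 0L
  gw <- compute_gwas(st, "D", "linear")
  expect_equal(gw$note[2], "monomorphic")
  expect_true(is.na(gw$se[2]))
  expect_warning(ld <- make_ld_matrix(st), "monomorphic")
  expect_equal(ld[1, 2], 0)
  expect_equal(diag(ld), setNames(rep(1, 3), colnames(ld)))
})
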