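test_that("reading a well-formed table yields validated records and uppercases alleles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS\tEA\tNEA\tEAF\tBETA\tSE\tP\tN",
               "rs1\t11\t100\ta\tt\t0.30\t0.87\t0.01\t1e-100\t8631",
               "rs2\t11\t200\tC\tG\t0.10\t-0.05\t0.02\t0.012\t8631",
               "rs3\t11\t300\tg\ta\t0.45\t0.00\t0.05\t1.0\t8631"), path)
  ss <- read_sumstats(path)
  expect_equal(nrow(ss), 3)
  expect_equal(nrow(attr(ss, "rejected")), 0)
  expect_equal(ss$effect_allele, c("A", "C", "G"))
  expect_equal(ss$other_allele, c("T", "G", "A"))
  expect_equal(ss$beta, c(0.87, -0.05, 0))
})

test_that("rows violating invariants are rejected with reasons, not silently kept", {
  df <- make_records(c("rs1", "rs2", "rs3", "rs4"))
  df$se[2] <- 0                    # se must be positive
  df$pval[3] <- 0                  # pval in (0, 1]
  df$eaf[4] <- 1.2                 # eaf in (0, 1)
  kept <- suppressMessages(validate_sumstats(df))
  expect_equal(kept$snp_id, "rs1")
  rej <- attr(kept, "rejected")
  expect_setequal(rej$snp_id, c("rs2", "rs3", "rs4"))
  expect_true(any(grepl("se", rej$reason)))
})

test_that("case/control totals must add up and duplicates are an error", {
  df <- make_records(c("rs1", "rs2"))
  df$n <- 100; df$n_case <- c(40L, 40L); df$n_control <- c(60L, 59L)
  kept <- suppressMessages(validate_sumstats(df))
  expect_equal(kept$snp_id, "rs1")
  dup <- make_records(c("rs1", "rs1"))
  expect_error(validate_sumstats(dup), class = "ratiomr_validation_error")
})

test_that("a missing required column is a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tNEA\tBETA\tP", "rs1\tC\tT\t0.1\t0.01"), path)
  expect_error(read_sumstats(path), "SE", class = "ratiomr_format_error")
})

test_that("write then read round-trips all fields for text-representable values", {
  x <- make_records(c("rs1", "rs2"), beta = c(0.5, -0.25),
                    se = c(0.125, 0.0625), eaf = c(0.25, 0.5),
                    pval = c(1e-8, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path)
  for (col in c("snp_id", "effect_allele", "other_allele", "eaf",
                "beta", "se", "pval", "n", "pos")) {
    expect_identical(unname(y[[col]]), unname(x[[col]]), label = col)
  }
})

test_that("harmonization aligns swapped alleles by negating beta and flipping eaf", {
  expo <- make_records("rs1", effect_allele = "C", other_allele = "T",
                       beta = 0.87)
  outc_same <- make_records("rs1", effect_allele = "C", other_allele = "T",
                            beta = 0.05, eaf = 0.3)
  h1 <- harmonize(expo, outc_same)
  expect_equal(h1$outcome_beta, 0.05)
  expect_false(h1$flipped)
  expect_equal(h1$dropped_reason, "none")

  outc_swap <- make_records("rs1", effect_allele = "T", other_allele = "C",
                            beta = 0.05, eaf = 0.3)
  h2 <- harmonize(expo, outc_swap)
  expect_equal(h2$outcome_beta, -0.05)
  expect_equal(h2$outcome_eaf, 0.7)
  expect_true(h2$flipped)
})

test_that("ambiguous palindromic SNPs and allele mismatches are dropped with reasons", {
  expo <- make_records(c("rs1", "rs2", "rs3"),
                       effect_allele = c("A", "C", "C"),
                       other_allele = c("T", "G", "T"),
                       eaf = c(0.50, 0.30, 0.30))
  outc <- make_records(c("rs1", "rs2", "rs3"),
                       effect_allele = c("A", "C", "A"),
                       other_allele = c("T", "G", "G"),
                       eaf = c(0.50, 0.30, 0.30))
  h <- harmonize(expo, outc)
  expect_equal(h$dropped_reason[h$snp_id == "rs1"], "palindromic_ambiguous")
  # C/G palindrome with eaf 0.30 outside the ambiguity window is kept
  expect_equal(h$dropped_reason[h$snp_id == "rs2"], "none")
  expect_equal(h$dropped_reason[h$snp_id == "rs3"], "allele_mismatch")
  # palindromic SNP with missing eaf can never be aligned
  expo$eaf <- NA_real_
  h2 <- harmonize(expo, outc)
  expect_equal(h2$dropped_reason[h2$snp_id == "rs1"], "palindromic_ambiguous")
})

test_that("SNPs absent from the outcome are omitted, not an error", {
  expo <- make_records(c("rs1", "rs2"))
  outc <- make_records("rs1", beta = 0.02)
  expect_message(h <- harmonize(expo, outc), "absent")
  expect_equal(h$snp_id, "rs1")
})

test_that("harmonization is idempotent", {
  expo <- make_records(c("rs1", "rs2"), effect_allele = c("C", "A"),
                       other_allele = c("T", "G"), beta = c(0.8, 0.3))
  outc <- make_records(c("rs1", "rs2"), effect_allele = c("T", "A"),
                       other_allele = c("C", "G"), beta = c(0.05, -0.02),
                       eaf = c(0.3, 0.2))
  h1 <- harmonize(expo, outc)
  # feed the harmonized outcome effects back as outcome records
  outc2 <- make_records(h1$snp_id, effect_allele = h1$effect_allele,
                        other_allele = h1$other_allele,
                        beta = h1$outcome_beta, se = h1$outcome_se,
                        eaf = h1$outcome_eaf)
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$outcome_beta, h1$outcome_beta)
  expect_equal(h2$outcome_eaf, h1$outcome_eaf)
  expect_false(any(h2$flipped))
})

test_that("relabelling alleles and negating both betas leaves MR estimates unchanged", {
  set.seed(11)
  expo <- make_records(sprintf("rs%d", 1:4), beta = runif(4, 0.2, 0.9),
                       se = 0.01)
  outc <- make_records(sprintf("rs%d", 1:4), beta = rnorm(4, 0.05, 0.02),
                       se = 0.02)
  est1 <- mr_ivw(harmonize(expo, outc))
  flip <- function(df) {
    tmp <- df$effect_allele
    df$effect_allele <- df$other_allele
    df$other_allele <- tmp
    df$beta <- -df$beta
    df$eaf <- 1 - df$eaf
    df
  }
  est2 <- mr_ivw(harmonize(flip(expo), flip(outc)))
  expect_equal(est2$beta, est1$beta, tolerance = 1e-12)
  expect_equal(est2$se, est1$se, tolerance = 1e-12)
})
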