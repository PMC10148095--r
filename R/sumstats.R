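#' Default column dialect for GWAS summary-statistic files
#'
#' Maps the package's internal field names to the column headers expected in
#' delimited summary-statistic files. Header matching is case-insensitive.
#' Override individual entries to read files with non-standard headers, e.g.
#' `sumstat_dialect(snp_id = "rsid", pval = "p_value")`.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n,n_case,n_control,trait_id,ancestry
#'   Column names in the file for each field.
#' @return A named character vector (internal name -> file column name).
#' @export
sumstat_dialect <- function(snp_id = "SNP", chrom = "CHR", pos = "POS",
                            effect_allele = "EA", other_allele = "NEA",
                            eaf = "EAF", beta = "BETA", se = "SE",
                            pval = "P", n = "N", n_case = "NCASE",
                            n_control = "NCONTROL", trait_id = "TRAIT",
                            ancestry = "ANCESTRY") {
  c(snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n,
    n_case = n_case, n_control = n_control, trait_id = trait_id,
    ancestry = ancestry)
}

sumstat_required <- c("snp_id", "effect_allele", "other_allele",
                      "beta", "se", "pval")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated (gzip transparently supported) summary-statistic
#' table, maps its columns through a dialect, uppercases alleles, and
#' validates every row against the summary-statistic invariants: `se > 0`,
#' `pval` in (0, 1], alleles over {A,C,G,T}, `eaf` in (0, 1) when present,
#' and `n_case + n_control == n` when all three are present. Rows failing
#' validation are dropped and reported; the returned tibble carries the
#' rejected rows (with reasons) in the `"rejected"` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector from [sumstat_dialect()].
#' @param delim Field delimiter (default tab).
#' @return A tibble of validated records with columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`, `n_case`, `n_control`, `trait_id`, `ancestry`.
#' @export
read_sumstats <- function(path, dialect = sumstat_dialect(), delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  lookup <- setNames(names(raw), toupper(names(raw)))
  missing_req <- sumstat_required[!toupper(dialect[sumstat_required]) %in% names(lookup)]
  if (length(missing_req) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(dialect[missing_req], collapse = ", ")),
          class = "ratiomr_format_error")
  }
  pick <- function(field, parse = identity) {
    col <- lookup[toupper(dialect[[field]])]
    if (is.na(col)) rep(NA_character_, nrow(raw)) else raw[[col]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(round(as.numeric(x))))
  out <- tibble(
    snp_id = pick("snp_id"),
    chrom = as.character(pick("chrom")),
    pos = int(pick("pos")),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    eaf = num(pick("eaf")),
    beta = num(pick("beta")),
    se = num(pick("se")),
    pval = num(pick("pval")),
    n = num(pick("n")),
    n_case = int(pick("n_case")),
    n_control = int(pick("n_control")),
    trait_id = pick("trait_id"),
    ancestry = pick("ancestry")
  )
  validate_sumstats(out, context = path)
}

#' Validate a tibble of summary-statistic records
#'
#' Applies the record-level invariants (see [read_sumstats()]) and drops
#' offending rows, attaching them with reasons as the `"rejected"`
#' attribute. Duplicate `(snp_id, trait_id)` pairs are an error.
#'
#' @param x Tibble with the internal summary-statistic columns.
#' @param context Label used in messages (e.g. the source file).
#' @return The validated tibble.
#' @export
validate_sumstats <- function(x, context = "sumstats") {
  allele_ok <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(x$snp_id) | x$snp_id == "", "missing snp_id")
  reason <- flag(!allele_ok(x$effect_allele) | !allele_ok(x$other_allele),
                 "invalid alleles")
  reason <- flag(is.na(x$beta), "non-numeric or missing beta")
  reason <- flag(is.na(x$se) | x$se <= 0, "se not positive")
  reason <- flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval outside (0,1]")
  reason <- flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf outside (0,1)")
  cc <- !is.na(x$n_case) & !is.na(x$n_control) & !is.na(x$n)
  reason <- flag(cc & (x$n_case + x$n_control != x$n),
                 "n_case + n_control != n")
  bad <- !is.na(reason)
  rejected <- mutate(x[bad, , drop = FALSE], reason = reason[bad],
                     row = which(bad))
  kept <- x[!bad, , drop = FALSE]
  dup <- duplicated(kept[, c("snp_id", "trait_id")])
  if (any(dup)) {
    abort(paste0(context, ": duplicated (snp_id, trait_id): ",
                 paste(unique(kept$snp_id[dup]), collapse = ", ")),
          class = "ratiomr_validation_error")
  }
  if (nrow(rejected) > 0) {
    inform(paste0(context, ": rejected ", nrow(rejected), " of ", nrow(x),
                  " rows (", paste(unique(rejected$reason), collapse = "; "), ")"))
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Write summary statistics in the standard dialect
#'
#' Inverse of [read_sumstats()]: writes a tab-separated file using the
#' dialect's column headers so that reading it back reproduces the records.
#'
#' @inheritParams read_sumstats
#' @param x Tibble of summary-statistic records.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, dialect = sumstat_dialect()) {
  out <- x[, intersect(names(dialect), names(x)), drop = FALSE]
  names(out) <- dialect[names(out)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Joins exposure and outcome records by `snp_id` and re-expresses the
#' outcome effect per copy of the exposure's effect allele. When the outcome
#' lists the alleles in swapped order, its beta is negated and its eaf
#' replaced by `1 - eaf` (`flipped = TRUE`). Palindromic SNPs (A/T or C/G)
#' whose eaf lies within `palindrome_eaf_window` of 0.5 on either trait —
#' or is missing — cannot be aligned by frequency and are dropped with
#' reason `"palindromic_ambiguous"`. SNPs whose allele sets do not match are
#' dropped with reason `"allele_mismatch"`. SNPs absent from the outcome are
#' omitted (not an error).
#'
#' @param exposure,outcome Tibbles of summary-statistic records
#'   (see [read_sumstats()]).
#' @param palindrome_eaf_window Half-width of the ambiguity window around
#'   eaf = 0.5 (default 0.08, i.e. drop when eaf is in (0.42, 0.58)).
#' @return A tibble of harmonized pairs: `snp_id`, `effect_allele`,
#'   `other_allele`, `exposure_beta`, `exposure_se`, `exposure_eaf`,
#'   `outcome_beta`, `outcome_se`, `outcome_eaf`, `flipped`,
#'   `dropped_reason` (`"none"` for usable pairs). Rows with a non-`"none"`
#'   reason must be excluded from estimation; [mr_ivw()] does so.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  exp_df <- tibble(
    snp_id = exposure$snp_id,
    effect_allele = toupper(exposure$effect_allele),
    other_allele = toupper(exposure$other_allele),
    exposure_beta = exposure$beta, exposure_se = exposure$se,
    exposure_eaf = if ("eaf" %in% names(exposure)) exposure$eaf else NA_real_
  )
  out_df <- tibble(
    snp_id = outcome$snp_id,
    o_ea = toupper(outcome$effect_allele),
    o_oa = toupper(outcome$other_allele),
    outcome_beta = outcome$beta, outcome_se = outcome$se,
    outcome_eaf = if ("eaf" %in% names(outcome)) outcome$eaf else NA_real_,
    outcome_id = if ("trait_id" %in% names(outcome)) outcome$trait_id
                 else NA_character_
  )
  # many-outcomes tables are allowed: one pair row per (snp, outcome trait)
  pairs <- inner_join(exp_df, out_df, by = "snp_id",
                      relationship = "many-to-many")
  dropped <- sum(!exp_df$snp_id %in% out_df$snp_id)
  if (dropped > 0) {
    inform(paste0("harmonize: ", dropped,
                  " exposure SNP(s) absent from outcome; omitted"))
  }
  same <- pairs$o_ea == pairs$effect_allele & pairs$o_oa == pairs$other_allele
  swap <- pairs$o_ea == pairs$other_allele & pairs$o_oa == pairs$effect_allele
  pal <- is_palindromic(pairs$effect_allele, pairs$other_allele)
  # for palindromic SNPs "swapped" order is strand-indistinguishable from
  # "same"; only frequency can align them
  ambiguous_eaf <- function(f) is.na(f) | abs(f - 0.5) < palindrome_eaf_window
  pal_bad <- pal & (ambiguous_eaf(pairs$exposure_eaf) |
                      ambiguous_eaf(pairs$outcome_eaf))
  flipped <- swap & !pal
  reason <- dplyr::case_when(
    !same & !swap ~ "allele_mismatch",
    pal_bad ~ "palindromic_ambiguous",
    .default = "none"
  )
  # palindromic with informative eaf: align by frequency, not allele order
  pal_flip <- pal & reason == "none" &
    ((pairs$exposure_eaf < 0.5) != (pairs$outcome_eaf < 0.5))
  flipped <- (flipped | pal_flip) & reason == "none"
  mutate(pairs,
         outcome_beta = ifelse(flipped, -.data$outcome_beta, .data$outcome_beta),
         outcome_eaf = ifelse(flipped, 1 - .data$outcome_eaf, .data$outcome_eaf),
         flipped = flipped,
         dropped_reason = reason,
         o_ea = NULL, o_oa = NULL)
}
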