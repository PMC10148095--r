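#' Read / write an LD matrix file
#'
#' Square tab-separated matrix of squared correlations (r-squared) with a
#' SNP-ID header row and a leading SNP-ID column. Validated to be
#' symmetric, with unit diagonal and entries in \[0, 1\].
#'
#' @param path File path.
#' @return [read_ld_matrix()] returns a numeric matrix with SNP-ID
#'   dimnames; [write_ld_matrix()] returns `path` invisibly.
#' @export
read_ld_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_ld_matrix(m)
}

#' @param ld Square r-squared matrix with SNP-ID dimnames.
#' @rdname read_ld_matrix
#' @export
write_ld_matrix <- function(ld, path) {
  df <- as_tibble(ld)
  df <- dplyr::bind_cols(tibble(SNP = rownames(ld)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

validate_ld_matrix <- function(m, tol = 1e-8) {
  if (nrow(m) != ncol(m)) abort("LD matrix not square",
                                class = "ratiomr_validation_error")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (!isTRUE(all.equal(rownames(m), colnames(m)))) {
    abort("LD matrix row/column SNP ids differ",
          class = "ratiomr_validation_error")
  }
  if (max(abs(m - t(m))) > tol) abort("LD matrix not symmetric",
                                      class = "ratiomr_validation_error")
  if (max(abs(diag(m) - 1)) > tol) abort("LD matrix diagonal must be 1",
                                         class = "ratiomr_validation_error")
  if (min(m) < -tol || max(m) > 1 + tol) {
    abort("LD r-squared values must lie in [0, 1]",
          class = "ratiomr_validation_error")
  }
  m
}

#' Select independent instruments by greedy LD clumping
#'
#' Standard P-value-ranked greedy clumping: repeatedly take the
#' smallest-P remaining SNP with `pval < p_thresh`, retain it, and remove
#' all remaining SNPs with squared LD `r2 >= r2_thresh` within `window_kb`
#' of it. Ties in P (including P-values underflowing to 0 at very strong
#' signals) are broken by descending |beta/se|, then by `snp_id`
#' (lexicographic), making the result invariant to input row order. A single genome-wide-significant
#' SNP yields an ordinary instrument of size one.
#'
#' @param records Tibble of exposure summary statistics (needs `snp_id`,
#'   `pval`, `beta`, `se`; `chrom`/`pos` when `window_kb` is finite;
#'   `eaf` for [variance_explained()]).
#' @param ld Square r-squared matrix with SNP-ID dimnames covering the
#'   candidates (see [read_ld_matrix()]).
#' @param p_thresh Selection P-value threshold (default `5e-8`).
#' @param r2_thresh LD pruning threshold (default `0.001`).
#' @param window_kb Clumping window in kilobases (default `10000`); SNPs
#'   outside the window are never pruned by LD. Use `Inf` to ignore
#'   positions.
#' @param missing_ld What to do with candidates absent from `ld`:
#'   `"drop"` them with a warning (default) or raise an `"error"`.
#' @return The retained records, classed `mr_instrument`, with attributes
#'   `p_thresh`, `r2_thresh`, `window_kb` and `excluded_regions`.
#' @export
clump <- function(records, ld, p_thresh = 5e-8, r2_thresh = 0.001,
                  window_kb = 10000, missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  cand <- filter(records, .data$pval < p_thresh)
  absent <- setdiff(cand$snp_id, rownames(ld))
  if (length(absent) > 0) {
    if (missing_ld == "error") {
      abort(paste0("SNP(s) missing from LD matrix: ",
                   paste(absent, collapse = ", ")),
            class = "ratiomr_ld_error")
    }
    warn(paste0("dropping ", length(absent), " SNP(s) missing from LD matrix"))
    cand <- filter(cand, !.data$snp_id %in% absent)
  }
  cand <- arrange(cand, .data$pval, dplyr::desc(abs(.data$beta / .data$se)),
                  .data$snp_id)
  have_pos <- is.finite(window_kb) && all(c("chrom", "pos") %in% names(cand)) &&
    !anyNA(cand$pos)
  keep <- character(0)
  remaining <- cand
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    keep <- c(keep, top$snp_id)
    rest <- remaining[-1, , drop = FALSE]
    if (nrow(rest) == 0) break
    in_ld <- ld[rest$snp_id, top$snp_id] >= r2_thresh
    if (have_pos) {
      near <- rest$chrom == top$chrom &
        abs(rest$pos - top$pos) <= window_kb * 1000
      in_ld <- in_ld & near
    }
    remaining <- rest[!in_ld, , drop = FALSE]
  }
  out <- filter(cand, .data$snp_id %in% keep)
  structure(out,
            class = c("mr_instrument", class(tibble())),
            p_thresh = p_thresh, r2_thresh = r2_thresh,
            window_kb = window_kb,
            excluded_regions = attr(records, "excluded_regions") %||% list())
}

parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9eE.+]+)-([0-9eE.+]+)$", region))[[1]]
  if (length(m) != 4) {
    abort(paste0("malformed region string: '", region,
                 "' (expected chrom:start-end)"),
          class = "ratiomr_parse_error")
  }
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (is.na(start) || is.na(end) || start > end) {
    abort(paste0("malformed region string: '", region, "'"),
          class = "ratiomr_parse_error")
  }
  list(chrom = m[2], start = start, end = end)
}

#' Exclude SNPs inside a genomic region
#'
#' Removes SNPs whose position falls inside the closed interval
#' `chrom:start-end` — e.g. to build instruments independent of a locus
#' with known widespread effects (the FADS-region exclusion analyses).
#'
#' @param records Tibble of summary statistics with `chrom` and `pos`.
#' @param region Region string `"chrom:start-end"` (1-based, closed).
#' @return `records` without the SNPs inside the region; the excluded
#'   region is appended to the `excluded_regions` attribute.
#' @export
exclude_region <- function(records, region) {
  r <- parse_region(region)
  inside <- records$chrom == as.character(r$chrom) &
    records$pos >= r$start & records$pos <= r$end
  inform(paste0("exclude_region: removed ", sum(inside), " SNP(s) in ", region))
  out <- records[!inside, , drop = FALSE]
  if (nrow(out) == 0) warn("exclude_region: no SNPs remain")
  attr(out, "excluded_regions") <-
    c(attr(records, "excluded_regions") %||% list(), list(r))
  out
}

#' Variance in the exposure explained by an instrument
#'
#' For SD-unit per-allele effects and effect-allele frequencies, the
#' proportion of exposure variance explained is
#' `sum over SNPs of 2 * eaf * (1 - eaf) * beta^2` (independent SNPs
#' assumed, as after clumping).
#'
#' @param instrument Tibble with `beta` (SD units) and `eaf`.
#' @return The explained proportion (numeric scalar).
#' @export
variance_explained <- function(instrument) {
  miss <- is.na(instrument$eaf)
  if (any(miss)) {
    warn(paste0("variance_explained: skipping ", sum(miss),
                " SNP(s) with missing eaf"))
  }
  f <- instrument$eaf[!miss]
  b <- instrument$beta[!miss]
  sum(2 * f * (1 - f) * b^2)
}
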