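# Independent oracles used across tests. These re-derive expected values by
# brute force or closed form through code paths separate from the package's
# implementations.

# Build a minimal summary-statistic record tibble with defaults.
make_records <- function(snp_id, effect_allele = "C", other_allele = "T",
                         eaf = 0.3, beta = 0.1, se = 0.01,
                         pval = 2 * pnorm(-abs(beta / se)),
                         chrom = "11", pos = seq_along(snp_id) * 1000L,
                         n = 10000, trait_id = "trait") {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
                 effect_allele = effect_allele, other_allele = other_allele,
                 eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                 n_case = NA_integer_, n_control = NA_integer_,
                 trait_id = trait_id, ancestry = "EUR")
}

# Exhaustive colocalisation oracle: enumerate every causal configuration
# (i, j) on the (m+1)^2 grid, i/j = 0 meaning "no causal variant for that
# trait", with per-configuration prior weights 1, p1, p2, p1*p2 (i != j)
# and p12 (i == j), and per-SNP Bayes factors computed from first
# principles as the ratio of marginal likelihoods of beta_hat under
# b ~ N(0, w) vs b = 0.
enum_coloc <- function(beta_a, se_a, beta_b, se_b,
                       p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       sd_a = 0.15, sd_b = 0.2) {
  bf <- function(bhat, se, w) {
    dnorm(bhat, 0, sqrt(w^2 + se^2)) / dnorm(bhat, 0, se)
  }
  A <- bf(beta_a, se_a, sd_a)
  B <- bf(beta_b, se_b, sd_b)
  m <- length(A)
  w <- matrix(0, m + 1, m + 1)
  for (i in 0:m) {
    for (j in 0:m) {
      bfa <- if (i == 0) 1 else A[i]
      bfb <- if (j == 0) 1 else B[j]
      prior <-
        if (i == 0 && j == 0) 1
        else if (j == 0) p1
        else if (i == 0) p2
        else if (i == j) p12
        else p1 * p2
      w[i + 1, j + 1] <- prior * bfa * bfb
    }
  }
  tot <- sum(w)
  c(h0 = w[1, 1] / tot,
    h1 = sum(w[-1, 1]) / tot,
    h2 = sum(w[1, -1]) / tot,
    h3 = (sum(w[-1, -1]) - sum(diag(w)[-1])) / tot,
    h4 = sum(diag(w)[-1]) / tot)
}

# Naive greedy clumping oracle: plain loops, no package code.
greedy_oracle <- function(records, ld, p_thresh, r2_thresh,
                          window_kb = Inf) {
  cand <- records[records$pval < p_thresh, ]
  o <- order(cand$pval, -abs(cand$beta / cand$se), cand$snp_id)
  cand <- cand[o, ]
  kept <- character(0)
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    kept <- c(kept, top$snp_id)
    drop <- rep(FALSE, nrow(cand))
    for (i in seq_len(nrow(cand))[-1]) {
      near <- !is.finite(window_kb) ||
        (cand$chrom[i] == top$chrom &&
           abs(cand$pos[i] - top$pos) <= window_kb * 1000)
      if (near && ld[cand$snp_id[i], top$snp_id] >= r2_thresh) drop[i] <- TRUE
    }
    drop[1] <- TRUE
    cand <- cand[!drop, , drop = FALSE]
  }
  sort(kept)
}

# DerSimonian-Laird step-by-step oracle.
dl_oracle <- function(beta, se) {
  w <- 1 / se^2
  mu_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - mu_fe)^2)
  k <- length(beta)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(beta = sum(ws * beta) / sum(ws), se = 1 / sqrt(sum(ws)),
       tau2 = tau2, Q = Q)
}
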