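#' Correlation between two studies' log-OR estimates induced by shared subjects
#'
#' Case-control studies that share subjects produce correlated effect
#' estimates; pooling them as if independent understates the pooled
#' variance. For log-OR estimates from two studies with case/control counts
#' `(n1a, n0a)` and `(n1b, n0b)` sharing `n_shared_controls` controls and
#' `n_shared_cases` cases, the shared-subject approximation to the
#' correlation is
#' \deqn{r = \frac{n^{shared}_0 \sqrt{n_{1a} n_{1b}/(n_{0a} n_{0b})} +
#'   n^{shared}_1 \sqrt{n_{0a} n_{0b}/(n_{1a} n_{1b})}}{\sqrt{N_a N_b}}}
#' clipped to \[0, 0.99\].
#'
#' @param study_a,study_b Lists (or one-row data frames) with `n_case` and
#'   `n_control`.
#' @param n_shared_controls,n_shared_cases Shared subject counts (each must
#'   not exceed either study's respective total).
#' @return Correlation in \[0, 0.99\].
#' @export
overlap_correlation <- function(study_a, study_b,
                                n_shared_controls = 0, n_shared_cases = 0) {
  n1a <- study_a$n_case; n0a <- study_a$n_control
  n1b <- study_b$n_case; n0b <- study_b$n_control
  if (n_shared_controls > min(n0a, n0b) || n_shared_cases > min(n1a, n1b)) {
    abort("shared counts exceed a study's totals",
          class = "ratiomr_validation_error")
  }
  Na <- n1a + n0a; Nb <- n1b + n0b
  r <- (n_shared_controls * sqrt(n1a * n1b / (n0a * n0b)) +
          n_shared_cases * sqrt(n0a * n0b / (n1a * n1b))) / sqrt(Na * Nb)
  min(max(r, 0), 0.99)
}

#' Declared sample overlap between pairs of studies
#'
#' @param study_a,study_b Character vectors of study ids (pairwise rows).
#' @param n_shared_cases,n_shared_controls Integer vectors of shared counts.
#' @return A tibble of class `overlap_spec`.
#' @export
overlap_spec <- function(study_a = character(), study_b = character(),
                         n_shared_cases = integer(),
                         n_shared_controls = integer()) {
  structure(tibble(study_a = study_a, study_b = study_b,
                   n_shared_cases = as.integer(n_shared_cases),
                   n_shared_controls = as.integer(n_shared_controls)),
            class = c("overlap_spec", class(tibble())))
}

# covariance matrix of study-level estimates given declared overlap
overlap_sigma <- function(estimates, overlap) {
  k <- nrow(estimates)
  R <- diag(k)
  if (!is.null(overlap) && nrow(overlap) > 0) {
    needed <- c("n_case", "n_control")
    if (!all(needed %in% names(estimates))) {
      abort("estimates need n_case and n_control columns to apply overlap",
            class = "ratiomr_validation_error")
    }
    idx <- setNames(seq_len(k), estimates$study_id)
    for (i in seq_len(nrow(overlap))) {
      a <- idx[overlap$study_a[i]]; b <- idx[overlap$study_b[i]]
      if (is.na(a) || is.na(b)) next
      r <- overlap_correlation(estimates[a, ], estimates[b, ],
                               n_shared_controls = overlap$n_shared_controls[i],
                               n_shared_cases = overlap$n_shared_cases[i])
      R[a, b] <- R[b, a] <- r
    }
  }
  diag(estimates$se) %*% R %*% diag(estimates$se)
}

#' Fixed-effects meta-analysis of MR estimates across studies
#'
#' Inverse-variance-weighted fixed-effects pooling of per-study estimates
#' of the same exposure-outcome effect. With declared sample overlap the
#' pooling is generalized least squares on the full covariance matrix
#' `Sigma_ij = r_ij se_i se_j`:
#' `beta = (1' Sigma^-1 1)^-1 1' Sigma^-1 b`, `var = (1' Sigma^-1 1)^-1` —
#' which reduces exactly to classical inverse-variance weighting when all
#' declared overlaps are zero. Between-study heterogeneity is reported as
#' Cochran's Q.
#'
#' @param estimates Tibble of `mr_estimate` rows (one per study; same
#'   exposure and outcome). Needs `n_case`/`n_control` columns when
#'   `overlap` is supplied.
#' @param overlap Optional [overlap_spec()] of shared-subject counts.
#' @return A one-row `mr_estimate` tibble, `method = "meta_fe"`.
#' @export
meta_fixed <- function(estimates, overlap = NULL) {
  k <- nrow(estimates)
  stopifnot(k >= 1)
  if (k == 1) return(estimates)
  Sigma <- overlap_sigma(estimates, overlap)
  ones <- rep(1, k)
  Si <- tryCatch(solve(Sigma), error = function(e) {
    abort("overlap covariance matrix is singular; reduce declared overlap",
          class = "ratiomr_conditioning_error")
  })
  v <- 1 / drop(ones %*% Si %*% ones)
  beta <- v * drop(ones %*% Si %*% estimates$beta)
  se <- sqrt(v)
  q <- cochran_q(estimates$beta, estimates$se)
  new_mr_estimate(beta, se, z_pval(beta, se), "meta_fe", sum(estimates$n_snps),
                  Q = q$Q, Q_df = q$df, Q_pval = q$pval,
                  exposure_id = estimates$exposure_id[1],
                  outcome_id = estimates$outcome_id[1],
                  study_id = paste(estimates$study_id, collapse = "+"))
}

#' Random-effects meta-analysis across outcomes
#'
#' DerSimonian-Laird random-effects pooling, used to combine MR estimates
#' across related outcomes (e.g. cancers of one biological system):
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights `w = 1/se^2`, then pooling with weights
#' `1/(se^2 + tau2)`. The heterogeneity P-value is reported alongside.
#'
#' @param estimates Tibble of `mr_estimate` rows (>= 2).
#' @return A one-row `mr_estimate` tibble, `method = "meta_re"`, with
#'   attribute `tau2` and heterogeneity `Q`, `Q_df`, `Q_pval`.
#' @export
meta_random <- function(estimates) {
  k <- nrow(estimates)
  if (k < 2) abort("random-effects pooling needs >= 2 estimates",
                   class = "ratiomr_insufficient_data")
  w <- 1 / estimates$se^2
  q <- cochran_q(estimates$beta, estimates$se)
  tau2 <- max(0, (q$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (estimates$se^2 + tau2)
  beta <- sum(ws * estimates$beta) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  out <- new_mr_estimate(beta, se, z_pval(beta, se), "meta_re",
                         sum(estimates$n_snps),
                         Q = q$Q, Q_df = q$df, Q_pval = q$pval,
                         exposure_id = estimates$exposure_id[1],
                         outcome_id = paste(estimates$outcome_id, collapse = "+"))
  attr(out, "tau2") <- tau2
  out
}

#' Z test for a difference between two MR estimates
#'
#' `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2 - 2 cov)` with a
#' two-sided normal P-value; used to compare findings between outcome
#' subtypes (e.g. distal vs proximal colorectal cancer). For more than two
#' groups use [cochran_q()] on the group estimates.
#'
#' @param est_a,est_b One-row tibbles with `beta` and `se`.
#' @param covariance Covariance between the two estimates (default 0).
#' @return A tibble with `z` and `pval`.
#' @export
difference_test <- function(est_a, est_b, covariance = 0) {
  v <- est_a$se^2 + est_b$se^2 - 2 * covariance
  if (v <= 0) abort("variance of difference is not positive",
                    class = "ratiomr_validation_error")
  z <- (est_a$beta - est_b$beta) / sqrt(v)
  tibble(z = z, pval = 2 * stats::pnorm(-abs(z)))
}

#' Outcome-level covariate table constructor
#'
#' One row per outcome with the characteristics used in heterogeneity
#' meta-regression: smoking-relatedness, inflammation-relatedness,
#' incidence, survival time, median age at diagnosis, stem-cell division
#' rate, and a biological-system grouping.
#'
#' @param path TSV file keyed by `cancer_id`.
#' @return Tibble keyed by `cancer_id`.
#' @export
read_cancer_covariates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Mixed-effects meta-regression of MR estimates on an outcome-level covariate
#'
#' Models outcome-level MR estimates as
#' `beta_c = gamma0 + gamma1 x_c + u_c + e_c`, with random effect
#' `u_c ~ N(0, tau2)` and known sampling variances `se_c^2`, one moderator
#' at a time. `tau2` is estimated by the method of moments
#' (`tau2 = max(0, (QE - (k - 2)) / tr(P))` with
#' `P = W - W X (X'WX)^-1 X'W` from the fixed-effects weighted fit), then
#' the coefficients are re-estimated by GLS with covariance
#' `diag(se^2 + tau2)` plus, when an overlap spec is supplied, off-diagonal
#' shared-subject terms `r_ij se_i se_j`. Continuous moderators are
#' standardized before fitting; the slope is tested by a Wald z test.
#'
#' @param estimates Tibble of `mr_estimate` rows, one per outcome, with an
#'   `outcome_id` column matching `covariates$cancer_id` (>= 4 rows).
#' @param covariates Outcome-level covariate tibble keyed by `cancer_id`.
#' @param moderator Name of the covariate column to test (string).
#' @param overlap Optional [overlap_spec()].
#' @param standardize_moderator Standardize a continuous moderator to mean
#'   0, SD 1 (default TRUE; logical moderators are coded 0/1 unscaled).
#' @return A `meta_regression` tibble with rows `intercept` and
#'   `moderator`: `estimate`, `se`, `z`, `pval`; attributes `tau2`, `QE`.
#' @export
meta_regression <- function(estimates, covariates, moderator, overlap = NULL,
                            standardize_moderator = TRUE) {
  df <- inner_join(estimates, covariates,
                   by = c(outcome_id = "cancer_id"))
  k <- nrow(df)
  if (k < 4) abort("meta-regression needs >= 4 outcomes",
                   class = "ratiomr_insufficient_data")
  x <- df[[moderator]]
  if (is.logical(x) || is.character(x) || is.factor(x)) {
    x <- as.numeric(as.factor(x)) - 1
  } else if (standardize_moderator) {
    x <- as.numeric(scale(x))
  }
  if (length(unique(x)) < 2 || sd(x) == 0) {
    abort(paste0("moderator '", moderator, "' is constant"),
          class = "ratiomr_rank_error")
  }
  X <- cbind(1, x)
  W <- diag(1 / df$se^2)
  XtWX <- crossprod(X, W %*% X)
  bfe <- solve(XtWX, crossprod(X, W %*% df$beta))
  resid <- df$beta - X %*% bfe
  QE <- drop(crossprod(resid, W %*% resid))
  P <- W - W %*% X %*% solve(XtWX, crossprod(X, W))
  tau2 <- max(0, (QE - (k - 2)) / sum(diag(P)))
  Sigma <- overlap_sigma(df, overlap) + diag(tau2, k)
  Si <- solve(Sigma)
  V <- solve(crossprod(X, Si %*% X))
  bgls <- unname(drop(V %*% crossprod(X, Si %*% df$beta)))
  se <- unname(sqrt(diag(V)))
  z <- bgls / se
  structure(tibble(term = c("intercept", moderator),
                   estimate = bgls, se = se, z = z,
                   pval = 2 * stats::pnorm(-abs(z))),
            class = c("meta_regression", class(tibble())),
            tau2 = tau2, QE = QE, k = k)
}
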