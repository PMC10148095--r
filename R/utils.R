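#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows
#'   rename group_by summarise ungroup across all_of n
#' @importFrom stats pnorm qnorm pchisq pt cor var sd rnorm runif rbinom
#'   setNames lm coef glm.fit binomial plogis complete.cases
#' @importFrom purrr map map_dbl map2 imap list_rbind
#' @importFrom utils head
NULL

# two-sided normal p-value from an estimate and its SE
z_pval <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# log(sum(exp(x))) without overflow; handles -Inf entries
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf (with warning) if a < b
log_diff_exp <- function(a, b) {
  if (b >= a) {
    if (b > a + 1e-12) {
      warn("log-space difference numerically negative; guarded to zero")
    }
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}

is_prob <- function(x) is.numeric(x) && all(x > 0 & x < 1)

`%||%` <- rlang::`%||%`
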