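#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param conf.level Confidence level for the interval.
#' @param exponentiate Report odds ratios instead of log ORs.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.mr_estimate <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = paste0(x$exposure_id, " on ", x$outcome_id),
    estimate = x$beta, std.error = x$se, statistic = x$beta / x$se,
    p.value = x$pval,
    conf.low = x$beta - z * x$se, conf.high = x$beta + z * x$se
  )
  if (exponentiate) {
    out <- mutate(out, across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @rdname tidy.mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, n_snps = x$n_snps,
         Q = x$Q, Q_df = x$Q_df, Q_pval = x$Q_pval)
}

#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = c("H0", "H1", "H2", "H3", "H4"),
         posterior = c(x$pp_h0, x$pp_h1, x$pp_h2, x$pp_h3, x$pp_h4))
}

#' @export
glance.coloc_result <- function(x, ...) {
  tibble(n_snps = x$n_snps, p1 = x$p1, p2 = x$p2, p12 = x$p12,
         colocalised = x$colocalised)
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble(term = c("total", "indirect", "direct"),
         estimate = c(x$total, x$indirect, x$direct),
         std.error = c(x$se_total, x$se_indirect, x$se_direct))
}

#' @export
tidy.meta_regression <- function(x, ...) {
  tibble(term = x$term, estimate = x$estimate, std.error = x$se,
         statistic = x$z, p.value = x$pval)
}

#' @export
glance.meta_regression <- function(x, ...) {
  tibble(tau2 = attr(x, "tau2"), QE = attr(x, "QE"), k = attr(x, "k"))
}

#' Forest plot of MR estimates
#'
#' Odds ratios (per SD of exposure) with confidence intervals, one row per
#' outcome/study.
#'
#' @param estimates Tibble of `mr_estimate` rows.
#' @param level Confidence level.
#' @param label Column to label rows by (default `outcome_id`).
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates, level = 0.95, label = "outcome_id") {
  df <- to_odds_ratio(estimates, level = level)
  df$label <- df[[label]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_lower,
                                          xmax = .data$or_upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per SD exposure", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability", x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_scan <- function(object, ...) {
  df <- mutate(object, logp = -log10(.data$pval))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome_id, y = .data$logp,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(df$alpha_adjusted[1]),
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "-log10 P") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
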