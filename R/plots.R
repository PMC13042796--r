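#' Forest-style plot of pooled relative risks
#'
#' @param object A `paf_meta` object from [pool_effects()].
#' @param ... Unused.
#' @return A ggplot: pooled RR with 95% CI per disease, colored by model.
#' @export
autoplot.paf_meta <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rr, y = .data$disease,
                               color = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Pooled relative risk (95% CI, log scale)", y = NULL,
                  color = "Model") +
    ggplot2::theme_minimal()
}

#' Instrument scatter with fitted causal slopes
#'
#' @param object A `paf_mr` object from [sensitivity_estimates()].
#' @param instruments The instrument tibble the estimates were fitted on.
#' @param ... Unused.
#' @return A ggplot: outcome vs exposure betas with one fitted line per
#'   method.
#' @export
autoplot.paf_mr <- function(object, instruments, ...) {
  est <- as_tibble(object)
  abline <- tibble(
    method = est$method,
    slope = est$slope,
    intercept = ifelse(est$method == "egger", est$intercept, 0)
  )
  ggplot2::ggplot(instruments,
                  ggplot2::aes(x = .data$beta_exposure, y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                   ymax = .data$beta_outcome + .data$se_outcome),
      color = "grey70", width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = abline,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   color = .data$method)) +
    ggplot2::labs(x = "Variant effect on puberty timing (years/allele)",
                  y = "Variant effect on disease (log-odds/allele)",
                  color = "Method") +
    ggplot2::theme_minimal()
}

#' Bar chart of attributable cases by disease and sex
#'
#' @param report A `burden_report` from [make_tables()].
#' @param ... Unused.
#' @return A ggplot of attributable cases (thousands, with 95% UI bars).
#' @export
plot_burden <- function(report, ...) {
  x <- report$by_sex_disease %>%
    filter(.data$sex != "total", .data$disease != "total")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cases_thousands,
                                  y = .data$disease, fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ui_low, xmax = .data$ui_high),
      position = ggplot2::position_dodge(width = 0.9), height = 0.3) +
    ggplot2::labs(x = "Attributable cases (thousands, 95% UI)", y = NULL,
                  fill = "Sex") +
    ggplot2::theme_minimal()
}
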