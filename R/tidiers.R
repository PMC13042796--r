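#' Tidy a meta-analysis pool
#'
#' @param x A `paf_meta` object from [pool_effects()].
#' @param ... Unused.
#' @return Tibble with one row per disease: estimate (`rr`), CI, model and
#'   heterogeneity statistics.
#' @export
tidy.paf_meta <- function(x, ...) {
  as_tibble(x) %>%
    select("disease", estimate = "rr", "ci_low", "ci_high", "p",
           "model", "k", "i2", "tau2")
}

#' One-row summary of a meta-analysis pool
#'
#' @param x A `paf_meta` object.
#' @param ... Unused.
#' @return One-row tibble: diseases pooled, total studies, how many pools
#'   fell to the random-effects model, median I-squared.
#' @export
glance.paf_meta <- function(x, ...) {
  tibble(
    n_diseases = nrow(x),
    n_studies = sum(x$k),
    n_random = sum(x$model == "random"),
    median_i2 = stats::median(x$i2)
  )
}

#' Tidy an MR estimate set
#'
#' @param x A `paf_mr` object from [sensitivity_estimates()].
#' @param ... Unused.
#' @return Tibble, one row per method: `estimate` (OR per 1-year delay),
#'   CI, p-value.
#' @export
tidy.paf_mr <- function(x, ...) {
  as_tibble(x) %>%
    select("disease", "direction", "method", estimate = "or_per_year",
           "ci_low", "ci_high", "p", "n_variants")
}

#' One-row summary of an MR estimate set
#'
#' @param x A `paf_mr` object.
#' @param ... Unused.
#' @return One-row tibble: IVW estimate and p, instrument count, Cochran's
#'   Q, Egger intercept p (pleiotropy) where available.
#' @export
glance.paf_mr <- function(x, ...) {
  ivw <- filter(as_tibble(x), .data$method == "ivw")
  egger <- filter(as_tibble(x), .data$method == "egger")
  tibble(
    disease = ivw$disease[1],
    or_per_year = ivw$or_per_year[1],
    p_ivw = ivw$p[1],
    n_variants = ivw$n_variants[1],
    q = ivw$q[1],
    p_egger_intercept = if (nrow(egger) > 0) egger$intercept_p[1] else NA_real_
  )
}
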