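## Meta-analysis of epidemiological effect estimates (OR/RR/HR on the log
## scale, treated as interchangeable ratio measures) with the pooling model
## chosen by the I-squared rule: fixed effect if I2 < 50, random effects
## (DerSimonian-Laird) otherwise.

check_effects <- function(effects, min_k = 1) {
  check_columns(effects, c("disease", "log_effect", "se"), "study-effect table")
  if (nrow(effects) < min_k) {
    abort(sprintf("need at least %d stud%s, got %d",
                  min_k, if (min_k == 1) "y" else "ies", nrow(effects)))
  }
  if (dplyr::n_distinct(effects$disease) > 1) {
    abort("all studies must share one disease; use pool_effects() to pool a multi-disease table")
  }
  if (any(effects$se <= 0)) abort("study standard errors must be positive")
  invisible(effects)
}

# Cochran's Q and I2 (%) from inverse-variance weights
heterogeneity <- function(y, w) {
  k <- length(y)
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  i2 <- if (q > 0) max(0, 100 * (q - (k - 1)) / q) else 0
  list(q = q, i2 = i2, k = k)
}

pooled_row <- function(disease, model, mu, se, q, i2, tau2, k) {
  tibble(
    disease = disease, model = model, k = k,
    log_rr = mu, se = se, rr = exp(mu),
    ci_low = exp(mu - Z95 * se), ci_high = exp(mu + Z95 * se),
    q = q, i2 = i2, tau2 = tau2,
    p = 2 * pnorm(-abs(mu / se))
  )
}

#' Fixed-effect (inverse-variance) pooling of study effects
#'
#' Pools log effect estimates with weights `1/se^2`. Cochran's Q and
#' I-squared are computed from the same weights.
#'
#' @param effects Tibble of studies for one disease with columns `disease`,
#'   `log_effect`, `se` (and optionally `study_id`, `effect_type`, `n`).
#' @return One-row tibble: `disease`, `model`, `k`, `log_rr`, `se`, `rr`,
#'   `ci_low`, `ci_high` (95% CI on the ratio scale), `q`, `i2`, `tau2`, `p`.
#' @seealso [pool_random()], [pool_auto()], [pool_effects()]
#' @examples
#' studies <- tibble::tibble(disease = "asthma",
#'                           log_effect = c(0.1, 0.3), se = c(0.1, 0.1))
#' pool_fixed(studies)
#' @export
pool_fixed <- function(effects) {
  check_effects(effects, min_k = 1)
  y <- effects$log_effect
  w <- 1 / effects$se^2
  het <- heterogeneity(y, w)
  pooled_row(effects$disease[1], "fixed",
             mu = sum(w * y) / sum(w), se = sqrt(1 / sum(w)),
             q = het$q, i2 = het$i2, tau2 = 0, k = het$k)
}

#' Random-effects (DerSimonian-Laird) pooling of study effects
#'
#' Between-study variance by the method of moments,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`; the pooled estimate then uses weights
#' `1/(se^2 + tau2)`. With homogeneous studies (Q <= k-1) tau2 truncates to 0
#' and the result equals the fixed-effect pool.
#'
#' @inheritParams pool_fixed
#' @return One-row tibble, as [pool_fixed()], with `model = "random"`.
#' @export
pool_random <- function(effects) {
  check_effects(effects, min_k = 2)
  y <- effects$log_effect
  w <- 1 / effects$se^2
  het <- heterogeneity(y, w)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (het$q - (het$k - 1)) / denom) else 0
  wr <- 1 / (effects$se^2 + tau2)
  pooled_row(effects$disease[1], "random",
             mu = sum(wr * y) / sum(wr), se = sqrt(1 / sum(wr)),
             q = het$q, i2 = het$i2, tau2 = tau2, k = het$k)
}

#' Pool study effects, choosing the model by the I-squared rule
#'
#' Computes I-squared from the fixed-effect Q and returns the fixed-effect
#' pool when I2 < 50 (strictly), the DerSimonian-Laird random-effects pool
#' otherwise. A single study is pooled fixed by convention (tau2 is
#' undefined at k = 1).
#'
#' @inheritParams pool_fixed
#' @return One-row tibble as [pool_fixed()]; the `model` column records the
#'   choice.
#' @export
pool_auto <- function(effects) {
  fixed <- pool_fixed(effects)
  if (fixed$k < 2 || fixed$i2 < 50) fixed else pool_random(effects)
}

#' Pool a multi-disease study table
#'
#' Applies [pool_auto()] (or a forced model) per disease and stacks the
#' results. The returned object carries class `paf_meta` so that [tidy()],
#' [glance()] and [ggplot2::autoplot()] apply.
#'
#' @param effects Study-effect tibble covering one or more diseases.
#' @param model `"auto"` (the I-squared rule), `"fixed"` or `"random"`.
#' @return A `paf_meta` tibble with one row per disease.
#' @examples
#' cfg <- sim_config(seed = 1)
#' pool_effects(simulate_study_effects(cfg))
#' @export
pool_effects <- function(effects, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  pool <- switch(model, auto = pool_auto, fixed = pool_fixed, random = pool_random)
  out <- effects %>%
    dplyr::group_split(.data$disease) %>%
    purrr::map(pool) %>%
    bind_rows() %>%
    arrange(.data$disease)
  class(out) <- c("paf_meta", class(out))
  out
}

#' Read a study-effect table from CSV
#'
#' Expects columns `disease`, `study_id`, `effect_type`, `effect`, `ci_low`,
#' `ci_high` and optionally `n`. The standard error is recovered from the
#' 95% CI on the log scale as `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param path Path to the CSV file.
#' @return Study-effect tibble with `log_effect` and `se` columns, ready for
#'   [pool_effects()].
#' @export
read_study_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("disease", "study_id", "effect_type", "effect",
                     "ci_low", "ci_high"), "study CSV")
  if (any(x$effect <= 0 | x$ci_low <= 0 | x$ci_high <= x$ci_low)) {
    abort("effects and CI bounds must be positive with ci_low < ci_high")
  }
  x %>% mutate(log_effect = log(.data$effect),
               se = (log(.data$ci_high) - log(.data$ci_low)) / (2 * Z95))
}
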