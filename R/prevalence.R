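## Three-tier exposure-prevalence pooling: inverse-variance within country,
## sample-size-by-case-count weighted average across countries within a
## region, and OLS regression on disease incidence for regions without
## surveys. Prevalence is treated as time-invariant over the exposure
## window; the lag between exposure and outcome year is metadata on the
## records, not a computation.

# binomial SE with an Agresti-Coull-style +2/+4 shift at the 0/1 boundary,
# where the plug-in SE would be 0
survey_se <- function(p, n) {
  p_adj <- ifelse(p <= 0 | p >= 1, (p * n + 2) / (n + 4), p)
  sqrt(p_adj * (1 - p_adj) / n)
}

check_surveys <- function(records) {
  check_columns(records, c("country", "sex", "prevalence", "n"),
                "prevalence-survey table")
  if (any(records$prevalence < 0 | records$prevalence > 1)) {
    abort("prevalence must lie in [0, 1]")
  }
  if (any(records$n < 1)) abort("survey sample sizes must be >= 1")
  invisible(records)
}

#' Pool prevalence surveys within one country and sex
#'
#' Inverse-variance pooling of survey prevalences using binomial standard
#' errors `sqrt(p(1-p)/n)`; surveys reporting exactly 0 or 1 get an
#' Agresti-Coull-style +2/+4 continuity shift so their weight stays finite.
#'
#' @param records Survey tibble sharing one `(country, sex)`; columns
#'   `country`, `sex`, `prevalence`, `n` (plus optional `region`, `period`).
#' @return One-row tibble: `country`, `sex`, `prevalence` (pooled), `n`
#'   (total), `se`, `k_surveys`.
#' @export
pool_within_country <- function(records) {
  check_surveys(records)
  if (nrow(distinct(records[c("country", "sex")])) > 1) {
    abort("pool_within_country(): records must share one (country, sex)")
  }
  se <- survey_se(records$prevalence, records$n)
  w <- 1 / se^2
  out <- tibble(
    country = records$country[1],
    sex = records$sex[1],
    prevalence = sum(w * records$prevalence) / sum(w),
    n = sum(records$n),
    se = sqrt(1 / sum(w)),
    k_surveys = nrow(records)
  )
  if ("region" %in% names(records)) out$region <- records$region[1]
  out
}

#' Geographical pooling of country prevalences into a region estimate
#'
#' Weighted average of country prevalence estimates with weights equal to
#' survey sample size times the country's disease case count:
#' `pe = sum(n_c * cases_c * p_c) / sum(n_c * cases_c)`.
#'
#' @param countries Tibble of pooled country records (one per country):
#'   columns `country`, `sex`, `prevalence`, `n` and optionally `se`,
#'   `region`.
#' @param case_counts Named numeric vector or tibble (`country`, `cases`)
#'   giving each country's case count.
#' @return One-row tibble: `region` (if present), `sex`, `pe`, `se`,
#'   `method = "geographical"`.
#' @export
pool_geographical <- function(countries, case_counts) {
  check_surveys(countries)
  if (is.data.frame(case_counts)) {
    check_columns(case_counts, c("country", "cases"), "case-count table")
    case_counts <- setNames(case_counts$cases, case_counts$country)
  }
  missing <- setdiff(countries$country, names(case_counts))
  if (length(missing) > 0) {
    abort(sprintf("no case count for countr%s: %s",
                  if (length(missing) == 1) "y" else "ies",
                  paste(missing, collapse = ", ")))
  }
  w <- countries$n * case_counts[countries$country]
  se <- if ("se" %in% names(countries)) countries$se else survey_se(countries$prevalence, countries$n)
  tibble(
    region = if ("region" %in% names(countries)) countries$region[1] else NA_character_,
    sex = countries$sex[1],
    pe = sum(w * countries$prevalence) / sum(w),
    se = sqrt(sum((w / sum(w))^2 * se^2)),
    method = "geographical"
  )
}

#' Risk-based prevalence for a region without surveys
#'
#' Fits an ordinary least-squares regression of pooled prevalence on disease
#' incidence across regions with known prevalence, then predicts at the
#' target region's incidence. Predictions are truncated to [0, 1] with a
#' warning.
#'
#' @param known Tibble of regions with known prevalence: columns `region`,
#'   `sex`, `pe`.
#' @param incidence_by_region Named numeric vector: incidence rate per
#'   region, covering all known regions and the target.
#' @param target_region Region label to predict.
#' @return One-row tibble: `region`, `sex`, `pe`, `se` (prediction SE),
#'   `method = "risk_based"`.
#' @export
pool_risk_based <- function(known, incidence_by_region, target_region) {
  check_columns(known, c("region", "sex", "pe"), "known-region table")
  if (nrow(known) < 2) abort("risk-based pooling needs >= 2 known regions")
  need <- c(known$region, target_region)
  missing <- setdiff(need, names(incidence_by_region))
  if (length(missing) > 0) {
    abort(sprintf("incidence missing for region(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- incidence_by_region[known$region]
  if (length(unique(x)) < 2) {
    abort("identical incidence across known regions: singular regression design")
  }
  fit <- lm(pe ~ incidence, data = tibble(pe = known$pe, incidence = as.numeric(x)))
  pr <- predict(fit, tibble(incidence = as.numeric(incidence_by_region[target_region])),
                se.fit = TRUE)
  pe <- as.numeric(pr$fit)
  if (pe < 0 || pe > 1) {
    warn(sprintf("risk-based prediction %.3f for region '%s' truncated to [0, 1]",
                 pe, target_region))
    pe <- min(max(pe, 0), 1)
  }
  tibble(region = target_region, sex = known$sex[1], pe = pe,
         se = as.numeric(pr$se.fit), method = "risk_based")
}

#' Full three-tier prevalence pooling
#'
#' Runs, per sex: (1) inverse-variance pooling of surveys within each
#' country, (2) geographical pooling of countries into their regions using
#' sample-size-by-case-count weights, and (3) risk-based regression
#' imputation for any region in `all_regions` with no surveys.
#'
#' @param surveys Survey tibble: `country`, `region`, `sex`, `survey_id`,
#'   `prevalence`, `n`.
#' @param case_counts Tibble `country`, `cases` (all-cause or per-disease
#'   counts, per the weighting choice).
#' @param incidence_by_region Named numeric vector of incidence rates used
#'   as the risk-based predictor (required only when a region lacks
#'   surveys).
#' @param all_regions Regions the output must cover; defaults to the
#'   regions present in `surveys`.
#' @return Tibble of region-level exposure prevalence: `region`, `sex`,
#'   `pe`, `se`, `method` (`"geographical"` or `"risk_based"`).
#' @examples
#' cfg <- sim_config(seed = 1)
#' surveys <- simulate_prevalence_surveys(cfg)
#' inc <- simulate_incidence(cfg)
#' @export
pool_prevalence <- function(surveys, case_counts, incidence_by_region = NULL,
                            all_regions = unique(surveys$region)) {
  check_surveys(surveys)
  check_columns(surveys, "region", "prevalence-survey table")

  by_country <- surveys %>%
    dplyr::group_split(.data$country, .data$sex) %>%
    purrr::map(pool_within_country) %>%
    bind_rows()

  geographical <- by_country %>%
    dplyr::group_split(.data$region, .data$sex) %>%
    purrr::map(pool_geographical, case_counts = case_counts) %>%
    bind_rows()

  gaps <- setdiff(all_regions, unique(geographical$region))
  if (length(gaps) > 0) {
    if (is.null(incidence_by_region)) {
      abort(sprintf("region(s) without surveys (%s) but no incidence_by_region supplied",
                    paste(gaps, collapse = ", ")))
    }
    imputed <- purrr::map(gaps, function(rg) {
      geographical %>%
        dplyr::group_split(.data$sex) %>%
        purrr::map(pool_risk_based, incidence_by_region = incidence_by_region,
                   target_region = rg) %>%
        bind_rows()
    }) %>% bind_rows()
    geographical <- bind_rows(geographical, imputed)
  }
  arrange(geographical, .data$region, .data$sex)
}

#' Read a prevalence-survey table from CSV
#'
#' Expects columns `country`, `region`, `sex`, `survey_id`, `prevalence`,
#' `n` and optionally `period`.
#'
#' @param path Path to the CSV file.
#' @return Survey tibble ready for [pool_prevalence()].
#' @export
read_survey_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("country", "region", "sex", "survey_id", "prevalence", "n"),
                "survey CSV")
  check_surveys(x)
  x
}
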