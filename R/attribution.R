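## Levin-formula attributable fractions applied to stratified incidence.
## PAFs are computed at region x sex level and applied uniformly across age
## (age variation enters through the incidence itself); attributable draws
## are cases draws times PAF, element-wise per draw.

#' Population attributable fraction (Levin's formula)
#'
#' `PAF = Pe (RR - 1) / (Pe (RR - 1) + 1)`, where `Pe` is the exposure
#' prevalence in the general population and `RR` the relative risk of the
#' exposed. Strictly increasing in both arguments for RR > 1. Protective
#' exposures (RR < 1) are refused by default: the attributable-fraction
#' framework here is for harmful exposures, and such diseases should be
#' excluded upstream by the causal gate.
#'
#' @param pe Exposure prevalence, in [0, 1]. Vectorized.
#' @param rr Relative risk, > 0. Vectorized.
#' @param allow_protective If `TRUE`, RR < 1 yields a negative PAF instead
#'   of an error.
#' @return Numeric vector of attributable fractions in [0, 1) (or
#'   (-Inf, 1) when `allow_protective`).
#' @examples
#' levin_paf(0.2, 2)   # 0.2/1.2
#' @export
levin_paf <- function(pe, rr, allow_protective = FALSE) {
  if (any(pe < 0 | pe > 1)) abort("pe must lie in [0, 1]")
  if (any(rr <= 0)) abort("rr must be positive")
  if (!allow_protective && any(rr < 1)) {
    abort("rr < 1 (protective): excluded from attributable-fraction calculation; gate upstream or set allow_protective = TRUE")
  }
  pe * (rr - 1) / (pe * (rr - 1) + 1)
}

#' Build the PAF table from prevalence and pooled relative risks
#'
#' Crosses region- and sex-specific exposure prevalence with disease-specific
#' pooled relative risks, restricted to diseases that passed the causal
#' gate, and evaluates Levin's formula for each (disease, sex, region).
#'
#' @param prevalence Region-prevalence tibble (`region`, `sex`, `pe`) from
#'   [pool_prevalence()].
#' @param pooled_rr Pooled-effect tibble (`disease`, `rr`) from
#'   [pool_effects()].
#' @param gated Character vector of diseases admitted by the causal gate;
#'   defaults to all diseases in `pooled_rr`.
#' @return PAF tibble: `disease`, `sex`, `region`, `pe`, `rr`, `paf`.
#' @export
paf_table <- function(prevalence, pooled_rr, gated = unique(pooled_rr$disease)) {
  check_columns(prevalence, c("region", "sex", "pe"), "prevalence table")
  check_columns(pooled_rr, c("disease", "rr"), "pooled RR table")
  rrs <- pooled_rr %>% filter(.data$disease %in% gated) %>% select("disease", "rr")
  tidyr::crossing(prevalence %>% select("region", "sex", "pe"), rrs) %>%
    mutate(paf = levin_paf(.data$pe, .data$rr)) %>%
    select("disease", "sex", "region", "pe", "rr", "paf")
}

#' Attributable cases from incidence cells and PAFs
#'
#' Joins each incidence stratum to its (disease, sex, region) PAF and
#' multiplies every case draw by it, preserving draw order. Strata whose
#' disease is absent from the PAF table (e.g. gated out, or a sex-specific
#' disease in the non-applicable sex) must not appear in `cells`; a missing
#' PAF is an error naming the stratum.
#'
#' @param cells Incidence tibble: `region`, `sex`, `age_group`, `disease`,
#'   `population`, draw columns `draw_*` (case counts).
#' @param pafs PAF tibble from [paf_table()].
#' @return Burden tibble: the stratum columns, `population`, `paf`, and
#'   attributable-case draw columns.
#' @export
attributable_cases <- function(cells, pafs) {
  check_columns(cells, c("region", "sex", "age_group", "disease", "population"),
                "incidence table")
  dc <- draw_cols(cells)
  if (length(dc) == 0) abort("incidence table carries no draw_* columns")
  key <- c("disease", "sex", "region")
  unmatched <- anti_join(distinct(cells[key]), pafs, by = key)
  if (nrow(unmatched) > 0) {
    u <- unmatched[1, ]
    abort(sprintf(
      "no PAF for stratum (disease=%s, sex=%s, region=%s)%s",
      u$disease, u$sex, u$region,
      if (nrow(unmatched) > 1) sprintf(" and %d more", nrow(unmatched) - 1) else ""))
  }
  left_join(cells, pafs %>% select(all_of(key), "paf"), by = key) %>%
    mutate(across(all_of(dc), ~ .x * .data$paf))
}

#' Aggregate burden cells draw-wise
#'
#' Sums case draws and populations over the strata not listed in `by`.
#' Sums happen within each draw index, so uncertainty intervals taken later
#' are intervals of the aggregate, and aggregation in any grouping order
#' gives identical totals. `by = character()` collapses to the world total.
#'
#' Special grouping keys: `"development"` maps regions/countries to the more
#' developed / less developed dichotomy before grouping; `"age_band"`
#' collapses 5-year age groups into the reporting bands 20-49, 50-69, 70+.
#'
#' @param cells Burden (or incidence) tibble with draw columns.
#' @param by Character vector of grouping keys, a subset of
#'   `c("disease", "sex", "age_group", "age_band", "region", "country",
#'   "development")`.
#' @return Aggregated tibble with grouping columns, `population`, and summed
#'   draw columns.
#' @export
aggregate_burden <- function(cells, by = character()) {
  dc <- draw_cols(cells)
  if (length(dc) == 0) abort("no draw_* columns to aggregate")
  if (anyNA(cells[dc])) abort("inconsistent draw counts across cells (NA draws)")
  x <- cells
  if ("development" %in% by) {
    ctry <- if ("country" %in% names(x)) x$country else NULL
    x <- mutate(x, development = development_status(.data$region, ctry))
  }
  if ("age_band" %in% by) {
    check_columns(x, "age_group", "burden table")
    x <- mutate(x, age_band = age_band_of(.data$age_group))
  }
  bad <- setdiff(by, names(x))
  if (length(bad) > 0) abort(sprintf("unknown grouping key(s): %s", paste(bad, collapse = ", ")))
  keep_pop <- "population" %in% names(x)
  x %>%
    group_by(across(all_of(by))) %>%
    summarise(
      across(all_of(if (keep_pop) "population" else character()), sum),
      across(all_of(dc), sum),
      .groups = "drop"
    )
}

# collapse 5-year GBD bands into the reporting bands 20-49 / 50-69 / 70+
age_band_of <- function(age_group) {
  start <- as.integer(sub("[-+].*$", "", age_group))
  dplyr::case_when(
    start >= 70 ~ "70+",
    start >= 50 ~ "50-69",
    start >= 20 ~ "20-49",
    TRUE ~ NA_character_
  )
}

#' Age-standardized incidence rate per 100,000 person-years
#'
#' Direct standardization: within each draw,
#' `ASIR = sum_a weight_a * (cases_a / population_a) * 100000` over the age
#' groups of the standard population. Cells are grouped by every non-age
#' stratum column present; each group must cover all standard age bands.
#'
#' @param cells Burden tibble with `age_group`, `population` and draw
#'   columns (one row per age group within each stratum).
#' @param std Standard-population tibble (`age_group`, `weight`) from
#'   [who_standard_population()].
#' @param per Rate denominator (default 100,000 person-years).
#' @return Tibble with the stratum columns and ASIR draw columns; summarize
#'   with [summarize_draws()].
#' @export
asir <- function(cells, std = who_standard_population(), per = 1e5) {
  check_columns(cells, c("age_group", "population"), "burden table")
  dc <- draw_cols(cells)
  if (length(dc) == 0) abort("no draw_* columns")
  strata <- setdiff(names(cells), c("age_group", "population", "paf", dc))
  gaps <- cells %>%
    group_by(across(all_of(strata))) %>%
    summarise(missing = paste(setdiff(std$age_group, .data$age_group), collapse = ", "),
              .groups = "drop") %>%
    filter(.data$missing != "")
  if (nrow(gaps) > 0) {
    abort(sprintf("age band(s) missing from standard population coverage: %s",
                  gaps$missing[1]))
  }
  cells %>%
    dplyr::inner_join(std, by = "age_group") %>%
    group_by(across(all_of(strata))) %>%
    summarise(across(all_of(dc), ~ sum(.data$weight * .x / .data$population) * per),
              .groups = "drop")
}
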