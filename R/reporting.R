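## Report assembly: the three stratified burden tables (sex x disease,
## development status x age band, geographic region), overall PAF by sex,
## and the end-to-end pipeline driver. All internal arithmetic is on
## unrounded draw-level values; rounding to one decimal (cases in
## thousands) happens only at the report layer.

round1 <- function(x) round(x, 1)

# summarize attributable-case draws in thousands, rounded at the edge
cases_table <- function(cells, by) {
  aggregate_burden(cells, by = by) %>%
    summarize_draws() %>%
    mutate(cases_thousands = round1(.data$point / 1e3),
           ui_low = round1(.data$ui_low / 1e3),
           ui_high = round1(.data$ui_high / 1e3)) %>%
    select(all_of(by), "cases_thousands", "ui_low", "ui_high")
}

#' Assemble the stratified burden report
#'
#' From attributable-case cells (and, optionally, the matching total
#' incidence cells for PAF columns), builds the three standard tables:
#' by sex and disease, by development status and broad age band, and by
#' geographic region; plus overall PAF by sex when totals are supplied.
#' Case counts are reported in thousands with one decimal; uncertainty
#' intervals are 95% draw percentiles. ASIR columns (per 100,000
#' person-years, age-standardized to the WHO world standard) are attached
#' where age structure is available.
#'
#' @param burden Attributable-case tibble from [attributable_cases()]
#'   (stratum columns + `population` + draw columns).
#' @param incidence Optional total-incidence tibble on the same strata; when
#'   given, PAF columns (attributable / total, in percent, from draw means)
#'   are included.
#' @param std Standard population for ASIR columns.
#' @return A `burden_report`: list of tibbles `by_sex_disease`,
#'   `by_development_age`, `by_region`, `overall_paf`, plus `metadata`.
#' @export
make_tables <- function(burden, incidence = NULL,
                        std = who_standard_population()) {
  dc <- draw_cols(burden)
  if (length(dc) == 0) abort("make_tables(): burden has no draw_* columns")

  # standardize over the age bands the burden actually covers (renormalized),
  # so partial adult ranges still report a rate on the standard scale
  std <- std[std$age_group %in% unique(burden$age_group), ]
  if (nrow(std) == 0) abort("make_tables(): no overlap between burden age groups and the standard population")
  std$weight <- std$weight / sum(std$weight)

  by_sex_disease <- bind_rows(
    cases_table(burden, c("disease", "sex")),
    cases_table(burden, "disease") %>% mutate(sex = "total"),
    cases_table(burden, "sex") %>% mutate(disease = "total"),
    cases_table(burden, character()) %>%
      mutate(disease = "total", sex = "total")
  ) %>% arrange(.data$disease, .data$sex)

  by_development_age <- bind_rows(
    cases_table(burden, c("disease", "development")) %>%
      rename(stratum = "development"),
    cases_table(burden, c("disease", "age_band")) %>%
      rename(stratum = "age_band"),
    cases_table(burden, "development") %>%
      rename(stratum = "development") %>% mutate(disease = "total"),
    cases_table(burden, "age_band") %>%
      rename(stratum = "age_band") %>% mutate(disease = "total")
  ) %>% arrange(.data$disease, .data$stratum)

  asir_region <- asir(
    aggregate_burden(burden, by = c("region", "age_group")), std = std) %>%
    summarize_draws(prefix = "asir_")
  by_region <- cases_table(burden, "region") %>%
    left_join(asir_region %>%
                mutate(across(dplyr::starts_with("asir_"), round1)),
              by = "region")

  overall_paf <- NULL
  if (!is.null(incidence)) {
    att <- aggregate_burden(burden, "sex") %>% summarize_draws()
    tot <- aggregate_burden(incidence, "sex") %>% summarize_draws()
    overall_paf <- left_join(att, tot, by = "sex",
                             suffix = c("_attributable", "_total")) %>%
      mutate(paf_percent = round1(100 * .data$point_attributable /
                                    .data$point_total)) %>%
      select("sex", "paf_percent")
  }

  structure(
    list(by_sex_disease = by_sex_disease,
         by_development_age = by_development_age,
         by_region = by_region,
         overall_paf = overall_paf,
         metadata = list(n_draws = length(dc),
                         generated = "pafburden::make_tables")),
    class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat("Attributable-burden report (", x$metadata$n_draws, " draws)\n", sep = "")
  cat("\n-- Cases by sex and disease (thousands, 95% UI) --\n")
  print(x$by_sex_disease, n = Inf)
  cat("\n-- Cases by development status and age band --\n")
  print(x$by_development_age, n = Inf)
  cat("\n-- Cases and ASIR by region --\n")
  print(x$by_region, n = Inf)
  if (!is.null(x$overall_paf)) {
    cat("\n-- Overall PAF by sex (%) --\n")
    print(x$overall_paf)
  }
  invisible(x)
}

#' Run the whole estimation chain on synthetic data
#'
#' Executes, under one seed: study-effect simulation and I-squared-gated
#' meta-analysis; forward and reverse two-sample MR per disease and the
#' causal gate; survey simulation and three-tier prevalence pooling (the
#' configured survey-free region goes through risk-based regression);
#' Levin PAFs; attributable cases on simulated incidence draws; and the
#' stratified report. Every intermediate is returned so any number in the
#' report can be traced.
#'
#' @param cfg A [sim_config()]. Its seed drives all stages.
#' @param propagate_rr_pe If `TRUE`, relative-risk and prevalence
#'   uncertainty is sampled with [sample_parameter_draws()] and multiplied
#'   into the PAF draw-wise; by default uncertainty enters only through the
#'   incidence draws.
#' @return A `paf_pipeline` list: `pooled_rr`, `mr_results`, `gate`,
#'   `prevalence`, `pafs`, `incidence`, `burden`, `report`, `log`,
#'   `metadata`.
#' @examples
#' res <- run_pipeline(sim_config(seed = 7, n_draws = 50))
#' res$report$by_region
#' @export
run_pipeline <- function(cfg, propagate_rr_pe = FALSE) {
  validate_sim_config(cfg)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  # 1. relative risks
  studies <- simulate_study_effects(cfg)
  pooled <- pool_effects(studies, model = "auto")
  for (i in seq_len(nrow(pooled))) {
    note("meta-analysis: %s pooled with %s model (I2 = %.1f)",
         pooled$disease[i], pooled$model[i], pooled$i2[i])
  }

  # 2. causal gate
  mr_results <- purrr::map(cfg$diseases, function(d) {
    bind_rows(
      sensitivity_estimates(simulate_instruments(cfg, d, "forward"),
                            seed = substream_seed(cfg$seed, paste0("wm_", d))),
      mr_ivw(simulate_instruments(cfg, d, "reverse"))
    )
  }) %>% bind_rows()
  gate <- gate_diseases(mr_results)
  gated <- filter(gate, .data$causal_gate)$disease
  note("causal gate: %d of %d diseases gated in (%s)",
       length(gated), length(cfg$diseases), paste(gated, collapse = ", "))

  # 3. exposure prevalence
  surveys <- simulate_prevalence_surveys(cfg)
  incidence <- simulate_incidence(cfg)
  case_counts <- incidence %>%
    group_by(.data$country) %>%
    summarise(cases = sum(.data$mean_cases), .groups = "drop")
  incidence_by_region <- incidence %>%
    group_by(.data$region) %>%
    summarise(rate = sum(.data$mean_cases) / sum(.data$population),
              .groups = "drop") %>%
    (function(d) setNames(d$rate, d$region))
  prevalence <- pool_prevalence(surveys, case_counts,
                                incidence_by_region = incidence_by_region,
                                all_regions = cfg$regions)
  for (rg in unique(filter(prevalence, .data$method == "risk_based")$region)) {
    note("prevalence: region '%s' had no surveys; risk-based regression used", rg)
  }

  # 4. PAFs and attributable cases
  pafs <- paf_table(prevalence, pooled, gated = gated)
  cells <- incidence %>%
    semi_join(tibble(disease = gated), by = "disease") %>%
    select(-"mean_cases", -"true_cases")
  burden <- attributable_cases(cells, pafs)

  if (propagate_rr_pe) {
    dc <- draw_cols(burden)
    key <- burden %>% distinct(.data$disease, .data$sex, .data$region) %>%
      left_join(pafs, by = c("disease", "sex", "region")) %>%
      left_join(pooled %>% select("disease", rr_se = "se"), by = "disease") %>%
      left_join(prevalence %>% select("region", "sex", pe_se = "se"),
                by = c("region", "sex"))
    paf_draws <- purrr::pmap(key, function(disease, sex, region, pe, rr, paf,
                                           rr_se, pe_se) {
      rrd <- sample_parameter_draws(rr, rr_se, length(dc),
                                    seed = substream_seed(cfg$seed, paste0("rr_", disease)),
                                    scale = "log")
      ped <- sample_parameter_draws(pe, pe_se / max(pe * (1 - pe), 1e-8),
                                    length(dc),
                                    seed = substream_seed(cfg$seed, paste0("pe_", region, sex)),
                                    scale = "logit")
      levin_paf(ped, pmax(rrd, 1))
    })
    key$.paf_draws <- paf_draws
    burden <- burden %>%
      left_join(key %>% select("disease", "sex", "region", ".paf_draws"),
                by = c("disease", "sex", "region"))
    m <- as.matrix(burden[dc]) / burden$paf *
      do.call(rbind, burden$.paf_draws)
    burden[dc] <- as_tibble(m)
    burden$.paf_draws <- NULL
    note("uncertainty: RR and Pe draws propagated into PAF")
  }

  report <- make_tables(burden, incidence = cells)
  structure(
    list(studies = studies, pooled_rr = pooled, mr_results = mr_results,
         gate = gate, surveys = surveys, prevalence = prevalence,
         pafs = pafs, incidence = incidence, burden = burden,
         report = report, log = log,
         metadata = list(seed = cfg$seed, n_draws = cfg$n_draws,
                         propagate_rr_pe = propagate_rr_pe)),
    class = "paf_pipeline")
}

#' @export
print.paf_pipeline <- function(x, ...) {
  cat("pafburden pipeline run (seed ", x$metadata$seed, ", ",
      x$metadata$n_draws, " draws)\n", sep = "")
  cat("Gated diseases:",
      paste(filter(x$gate, .data$causal_gate)$disease, collapse = ", "), "\n")
  cat("Log:\n")
  cat(paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}
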