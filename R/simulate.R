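## Synthetic-data generator with known ground truth for every stage:
## epidemiological study effects, GWAS instrument sets, prevalence surveys,
## and stratified incidence with Monte-Carlo draws. One global seed;
## per-table substreams derived deterministically from it.

default_diseases <- c("asthma", "type2_diabetes", "ischemic_heart_disease",
                      "stroke", "testicular_cancer", "uterine_cancer",
                      "depression")

# causal slopes (log-OR per 1-year delay in puberty timing) matching
# published per-year risk reductions of roughly 5-19%
default_mr_slopes <- c(
  asthma = log(1 - 0.054), type2_diabetes = log(1 - 0.187),
  ischemic_heart_disease = log(1 - 0.067), stroke = log(1 - 0.112),
  testicular_cancer = log(1 - 0.161), uterine_cancer = log(1 - 0.158),
  depression = log(1 - 0.053)
)

# relative risks of disease among the early-maturing: with Pe around
# 0.10-0.25 these give PAFs in the low single-digit percents
default_rrs <- c(
  asthma = 1.20, type2_diabetes = 1.25, ischemic_heart_disease = 1.15,
  stroke = 1.18, testicular_cancer = 1.35, uterine_cancer = 1.40,
  depression = 1.22
)

default_regions <- c("East Asia and Pacific", "Europe and Central Asia",
                     "Latin America and Caribbean", "Middle East and North Africa",
                     "North America", "South Asia", "Sub-Saharan Africa")

#' Configuration of the synthetic world
#'
#' Collects every ground-truth parameter the generators need: true relative
#' risks, true causal slopes, true prevalences, stratum populations, and the
#' noise settings of each stage. Identical configurations (including the
#' seed) produce byte-identical tables from every `simulate_*()` function.
#'
#' @param seed Integer global seed; each generator derives its own
#'   deterministic substream from it.
#' @param regions Region labels. The last region in `survey_free_regions`
#'   (default: the last region) is generated without surveys so the
#'   risk-based pooling path is exercised.
#' @param n_countries_per_region Countries generated per region.
#' @param diseases Disease labels.
#' @param true_rr Named vector: true relative risk per disease (> 0).
#' @param true_mr_slope Named vector: true causal slope per disease (log-OR
#'   per 1-year delay in puberty timing; negative = early maturation harmful).
#' @param true_reverse_slope Named vector for the reverse MR direction
#'   (default 0 for every disease: no reverse causation).
#' @param true_prevalence_female,true_prevalence_male Baseline exposure
#'   prevalence by sex; per-country values are spread deterministically
#'   around these.
#' @param n_instruments Instruments per disease.
#' @param n_studies_per_disease Epidemiological studies per disease.
#' @param heterogeneity_tau Between-study SD of true log effects.
#' @param study_se_range Range of per-study sampling SEs.
#' @param n_surveys_per_country Surveys per (country, sex).
#' @param survey_n_range Range of survey sample sizes.
#' @param survey_free_regions Regions generated without surveys.
#' @param n_draws Monte-Carlo draws on incidence (>= 2).
#' @param draw_cv Coefficient of variation of the log-normal draw noise
#'   around each incidence mean (0 = degenerate draws).
#' @param age_groups Ordered 5-year age bands (adult bands by default).
#' @param base_rate Baseline annual incidence rate per person-year from
#'   which disease- and age-specific rates are scaled.
#' @param population_per_stratum Person-years in each
#'   region x country x sex x age stratum.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 42, n_draws = 100)
#' @export
sim_config <- function(seed = 1,
                       regions = default_regions,
                       n_countries_per_region = 2,
                       diseases = default_diseases,
                       true_rr = default_rrs[diseases],
                       true_mr_slope = default_mr_slopes[diseases],
                       true_reverse_slope = setNames(rep(0, length(diseases)), diseases),
                       true_prevalence_female = 0.18,
                       true_prevalence_male = 0.12,
                       n_instruments = 30,
                       n_studies_per_disease = 10,
                       heterogeneity_tau = 0.1,
                       study_se_range = c(0.05, 0.25),
                       n_surveys_per_country = 2,
                       survey_n_range = c(2000, 20000),
                       survey_free_regions = regions[length(regions)],
                       n_draws = 1000,
                       draw_cv = 0.12,
                       age_groups = c("20-24", "25-29", "30-34", "35-39",
                                      "40-44", "45-49", "50-54", "55-59",
                                      "60-64", "65-69", "70-74", "75-79",
                                      "80-84", "85+"),
                       base_rate = 0.002,
                       population_per_stratum = 5e5) {
  names(true_rr) <- names(true_rr) %||% diseases
  names(true_mr_slope) <- names(true_mr_slope) %||% diseases
  names(true_reverse_slope) <- names(true_reverse_slope) %||% diseases
  cfg <- list(
    seed = as.integer(seed), regions = regions,
    n_countries_per_region = n_countries_per_region,
    diseases = diseases,
    true_rr = true_rr, true_mr_slope = true_mr_slope,
    true_reverse_slope = true_reverse_slope,
    true_prevalence_female = true_prevalence_female,
    true_prevalence_male = true_prevalence_male,
    n_instruments = n_instruments,
    n_studies_per_disease = n_studies_per_disease,
    heterogeneity_tau = heterogeneity_tau,
    study_se_range = study_se_range,
    n_surveys_per_country = n_surveys_per_country,
    survey_n_range = survey_n_range,
    survey_free_regions = survey_free_regions,
    n_draws = as.integer(n_draws), draw_cv = draw_cv,
    age_groups = age_groups, base_rate = base_rate,
    population_per_stratum = population_per_stratum
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_config <- function(cfg) {
  if (any(cfg$true_rr <= 0)) abort("true_rr must be positive")
  if (setdiff(cfg$diseases, names(cfg$true_rr)) %>% length() > 0) {
    abort("true_rr must name every disease")
  }
  for (p in c(cfg$true_prevalence_female, cfg$true_prevalence_male)) {
    if (p < 0 || p > 1) abort("true prevalences must lie in [0, 1]")
  }
  if (cfg$n_draws < 2) abort("n_draws must be >= 2")
  if (cfg$heterogeneity_tau < 0) abort("heterogeneity_tau must be >= 0")
  if (cfg$n_studies_per_disease < 1) abort("n_studies_per_disease must be >= 1")
  if (cfg$n_instruments < 1) abort("n_instruments must be >= 1")
  starts <- as.integer(sub("[-+].*$", "", cfg$age_groups))
  if (is.unsorted(starts, strictly = TRUE)) {
    abort("age_groups must be ordered, non-overlapping bands")
  }
  invisible(cfg)
}

# country labels: "<region> C1", "<region> C2", ...
sim_countries <- function(cfg) {
  tidyr::crossing(region = cfg$regions,
                  idx = seq_len(cfg$n_countries_per_region)) %>%
    mutate(country = paste0(.data$region, " C", .data$idx)) %>%
    select("region", "country")
}

# deterministic per-(country, sex) true prevalence: baseline spread by a
# fixed +/-30% factor across countries so countries genuinely differ
sim_true_prevalence <- function(cfg) {
  countries <- sim_countries(cfg)
  k <- nrow(countries)
  spread <- if (k > 1) seq(-0.3, 0.3, length.out = k) else 0
  tidyr::crossing(countries, sex = c("female", "male")) %>%
    group_by(.data$sex) %>%
    mutate(true_p = pmin(0.95, pmax(0.005,
      ifelse(.data$sex == "female", cfg$true_prevalence_female,
             cfg$true_prevalence_male) * (1 + spread[dplyr::row_number()])))) %>%
    ungroup()
}

#' Simulate epidemiological study effects
#'
#' Per disease, `n_studies_per_disease` studies: the study-level true log
#' effect is normal around `log(true_rr)` with SD `heterogeneity_tau`; the
#' observed log effect adds sampling noise with a per-study SE drawn
#' uniformly from `study_se_range`. Effect-type tags (OR/RR/HR) cycle
#' deterministically; the CI is consistent with the SE.
#'
#' @param cfg A [sim_config()].
#' @return Study-effect tibble: `disease`, `study_id`, `effect_type`,
#'   `log_effect`, `se`, `effect`, `ci_low`, `ci_high`, `n`.
#' @export
simulate_study_effects <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "study_effects"))
  purrr::map(cfg$diseases, function(d) {
    k <- cfg$n_studies_per_disease
    se <- runif(k, cfg$study_se_range[1], cfg$study_se_range[2])
    theta <- rnorm(k, log(cfg$true_rr[[d]]), cfg$heterogeneity_tau)
    y <- rnorm(k, theta, se)
    tibble(
      disease = d,
      study_id = sprintf("%s_study_%02d", d, seq_len(k)),
      effect_type = c("OR", "RR", "HR")[(seq_len(k) - 1) %% 3 + 1],
      log_effect = y, se = se,
      effect = exp(y),
      ci_low = exp(y - Z95 * se), ci_high = exp(y + Z95 * se),
      n = round(4 / se^2)
    )
  }) %>% bind_rows()
}

#' Simulate a GWAS instrument set for one disease
#'
#' Exposure betas (years of puberty-timing delay per allele) are drawn
#' half-normal, with SEs giving genome-wide-significant instruments;
#' outcome betas are `slope x beta_exposure` plus normal noise at
#' `se_outcome`. Instruments are mutually independent (no LD).
#'
#' @param cfg A [sim_config()].
#' @param disease Disease label (must be in `cfg$diseases`).
#' @param direction `"forward"` uses `true_mr_slope`; `"reverse"` uses
#'   `true_reverse_slope`.
#' @return Instrument tibble: `disease`, `direction`, `variant_id`,
#'   `beta_exposure`, `se_exposure`, `p_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @export
simulate_instruments <- function(cfg, disease,
                                 direction = c("forward", "reverse")) {
  validate_sim_config(cfg)
  direction <- match.arg(direction)
  if (!disease %in% cfg$diseases) abort(sprintf("unknown disease '%s'", disease))
  slope <- if (direction == "forward") cfg$true_mr_slope[[disease]]
           else cfg$true_reverse_slope[[disease]]
  set.seed(substream_seed(cfg$seed, paste0("instruments_", direction, "_", disease)))
  m <- cfg$n_instruments
  # genome-wide-significant biobank-scale instruments: exposure effects of
  # 0.04-0.25 years/allele, outcome log-odds SEs around 0.01
  beta_exp <- abs(rnorm(m, 0, 0.08)) + 0.04
  se_exp <- runif(m, 0.004, 0.010)
  se_out <- runif(m, 0.006, 0.012)
  tibble(
    disease = disease, direction = direction,
    variant_id = sprintf("rs%06d", seq_len(m)),
    beta_exposure = beta_exp, se_exposure = se_exp,
    p_exposure = 2 * pnorm(-abs(beta_exp / se_exp)),
    beta_outcome = rnorm(m, slope * beta_exp, se_out),
    se_outcome = se_out
  )
}

#' Simulate prevalence surveys
#'
#' Per (country, sex) outside the survey-free regions,
#' `n_surveys_per_country` surveys: sample size uniform in `survey_n_range`,
#' observed prevalence binomial around the country's true prevalence.
#' Regions in `cfg$survey_free_regions` get no surveys, so the risk-based
#' pooling path is exercised downstream.
#'
#' @param cfg A [sim_config()].
#' @return Survey tibble: `country`, `region`, `sex`, `survey_id`,
#'   `prevalence`, `n`, `period`, `true_p`.
#' @export
simulate_prevalence_surveys <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "prevalence_surveys"))
  truth <- sim_true_prevalence(cfg) %>%
    filter(!.data$region %in% cfg$survey_free_regions)
  tidyr::crossing(truth, survey = seq_len(cfg$n_surveys_per_country)) %>%
    mutate(
      n = round(runif(dplyr::n(), cfg$survey_n_range[1], cfg$survey_n_range[2])),
      prevalence = rbinom(dplyr::n(), .data$n, .data$true_p) / .data$n,
      survey_id = sprintf("%s_%s_s%d", .data$country, .data$sex, .data$survey),
      period = "1960s-2000s"
    ) %>%
    select("country", "region", "sex", "survey_id", "prevalence", "n",
           "period", "true_p")
}

#' Simulate stratified incidence with Monte-Carlo draws
#'
#' Per region x country x sex x age x disease cell: a true case count
#' (base rate scaled by deterministic region-, disease- and age-specific
#' multipliers times the stratum population), an observed estimate
#' `mean_cases` that is one log-normal realization around the truth, and
#' `n_draws` mean-preserving log-normal draws around the observed estimate
#' with coefficient of variation `draw_cv` (the posterior-draw emulation;
#' `draw_cv = 0` collapses draws onto the estimate and the estimate onto
#' the truth). Draw columns are ordered `draw_1..draw_n`; index k is a
#' coherent scenario across cells.
#'
#' Sex-specific diseases appear only in the applicable sex (testicular
#' cancer: male; uterine cancer: female).
#'
#' @param cfg A [sim_config()].
#' @return Incidence tibble: `region`, `country`, `sex`, `age_group`,
#'   `disease`, `population`, `true_cases`, `mean_cases`, `draw_1..draw_n`.
#' @export
simulate_incidence <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "incidence"))
  ages <- cfg$age_groups
  age_mult <- setNames(seq(0.6, 1.8, length.out = length(ages)), ages)
  dis_mult <- setNames(seq(0.5, 2.0, length.out = length(cfg$diseases)),
                       sort(cfg$diseases))
  # deterministic between-region differences so regional rates genuinely vary
  reg_mult <- setNames(seq(0.7, 1.4, length.out = length(cfg$regions)),
                       cfg$regions)
  cells <- tidyr::crossing(sim_countries(cfg), sex = c("female", "male"),
                           age_group = ages, disease = cfg$diseases) %>%
    filter(!(.data$disease == "testicular_cancer" & .data$sex == "female"),
           !(.data$disease == "uterine_cancer" & .data$sex == "male")) %>%
    mutate(
      population = cfg$population_per_stratum,
      true_cases = unname(cfg$base_rate * age_mult[.data$age_group] *
        dis_mult[.data$disease] * reg_mult[.data$region] * .data$population)
    ) %>%
    arrange(.data$region, .data$country, .data$sex, .data$age_group,
            .data$disease)
  nd <- cfg$n_draws
  sigma <- sqrt(log(1 + cfg$draw_cv^2))
  # the observed estimate is itself one noisy realization around the truth;
  # draws then sample the posterior around that estimate, so 95% draw
  # intervals have honest coverage of the true cases
  obs <- exp(sigma * rnorm(nrow(cells)) - sigma^2 / 2)
  cells$mean_cases <- cells$true_cases * obs
  z <- matrix(rnorm(nrow(cells) * nd), nrow = nrow(cells), ncol = nd)
  draws <- cells$mean_cases * exp(sigma * z - sigma^2 / 2)
  colnames(draws) <- paste0("draw_", seq_len(nd))
  dplyr::bind_cols(cells, as_tibble(draws))
}

#' Write the four synthetic input tables to CSV
#'
#' Materializes study effects, instrument sets (forward and reverse, all
#' diseases), prevalence surveys and incidence as CSV files in `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  instruments <- purrr::map(cfg$diseases, function(d) {
    bind_rows(simulate_instruments(cfg, d, "forward"),
              simulate_instruments(cfg, d, "reverse"))
  }) %>% bind_rows()
  paths <- c(
    studies = file.path(dir, "study_effects.csv"),
    instruments = file.path(dir, "instruments.csv"),
    surveys = file.path(dir, "prevalence_surveys.csv"),
    incidence = file.path(dir, "incidence.csv")
  )
  readr::write_csv(simulate_study_effects(cfg), paths["studies"])
  readr::write_csv(instruments, paths["instruments"])
  readr::write_csv(simulate_prevalence_surveys(cfg), paths["surveys"])
  readr::write_csv(simulate_incidence(cfg), paths["incidence"])
  invisible(paths)
}
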