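# Small synthetic worlds shared across test files. All built in code;
# nothing on disk.

# compact world: 2 regions x 1 country, 2 diseases, 4 adult age bands
tiny_config <- function(seed = 1, n_draws = 40,
                        true_rr = c(asthma = 1.2, stroke = 1.3),
                        true_mr_slope = c(asthma = -0.06, stroke = -0.12),
                        n_studies_per_disease = 6, ...) {
  sim_config(
    seed = seed,
    regions = c("Alpha", "Beta"),
    n_countries_per_region = 1,
    diseases = c("asthma", "stroke"),
    true_rr = true_rr,
    true_mr_slope = true_mr_slope,
    n_instruments = 20,
    n_studies_per_disease = n_studies_per_disease,
    survey_free_regions = character(),
    n_draws = n_draws,
    age_groups = c("20-24", "25-29", "30-34", "35-39"),
    ...
  )
}

# hand-rolled incidence cells with known draws
toy_cells <- function() {
  tibble::tibble(
    region = "Alpha", country = "Alpha C1",
    sex = c("female", "female"),
    age_group = c("20-24", "25-29"),
    disease = "asthma",
    population = c(1000, 2000),
    draw_1 = c(10, 40), draw_2 = c(20, 60), draw_3 = c(30, 80)
  )
}

toy_pafs <- function(paf = 0.1) {
  tibble::tibble(disease = "asthma", sex = "female", region = "Alpha",
                 pe = 0.2, rr = 2, paf = paf)
}

expect_draws_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.matrix(a[draw_cols(a)]), as.matrix(b[draw_cols(b)]),
               tolerance = tol, ignore_attr = TRUE)
}
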