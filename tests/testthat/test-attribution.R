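test_that("Levin's formula matches direct arithmetic and its boundary cases", {
  expect_equal(levin_paf(0, 5), 0)
  expect_equal(levin_paf(0.7, 1), 0)
  expect_equal(levin_paf(0.2, 2), 0.2 / 1.2, tolerance = 1e-15)
  expect_equal(levin_paf(0.5, 3), 1 / 2, tolerance = 1e-15)

  expect_error(levin_paf(-0.1, 2), "\\[0, 1\\]")
  expect_error(levin_paf(0.2, 0), "positive")
  expect_error(levin_paf(0.2, 0.8), "protective")
  expect_lt(levin_paf(0.2, 0.8, allow_protective = TRUE), 0)
})

test_that("attributable cases scale every draw by the stratum PAF", {
  cells <- toy_cells()
  out <- attributable_cases(cells, toy_pafs(paf = 0.1))
  # hand multiplication oracle
  expect_equal(out$draw_1, c(1, 4))
  expect_equal(out$draw_2, c(2, 6))
  expect_equal(out$draw_3, c(3, 8))

  zero <- attributable_cases(cells, toy_pafs(paf = 0))
  expect_true(all(as.matrix(zero[draw_cols(zero)]) == 0))

  # attributable never exceeds total, draw-wise
  expect_true(all(as.matrix(out[draw_cols(out)]) <=
                    as.matrix(cells[draw_cols(cells)])))

  # missing stratum is an error naming it
  orphan <- dplyr::mutate(cells, disease = "stroke")
  expect_error(attributable_cases(orphan, toy_pafs()), "stroke")
})

test_that("PAF is strictly monotone in prevalence and relative risk", {
  pe <- seq(0.01, 0.99, length.out = 100)
  rr <- seq(1.01, 5, length.out = 100)
  for (r in c(1.2, 2, 4)) {
    expect_true(all(diff(levin_paf(pe, r)) > 0))
  }
  for (p in c(0.05, 0.3, 0.9)) {
    expect_true(all(diff(levin_paf(p, rr)) > 0))
  }
})

test_that("draw-wise aggregation is additive in any grouping order", {
  cfg <- tiny_config(seed = 8, n_draws = 20)
  inc <- simulate_incidence(cfg)
  cells <- dplyr::select(inc, -mean_cases, -true_cases)

  total_direct <- aggregate_burden(cells, by = character())
  via_region <- aggregate_burden(aggregate_burden(cells, c("region", "sex", "age_group")),
                                 by = character())
  via_disease <- aggregate_burden(aggregate_burden(cells, c("disease", "age_group")),
                                  by = character())
  expect_draws_equal(total_direct, via_region)
  expect_draws_equal(total_direct, via_disease)

  # single cell: identity
  one <- cells[3, ]
  agg1 <- aggregate_burden(one, c("region", "country", "sex", "age_group", "disease"))
  expect_draws_equal(agg1, one)

  # special keys resolve
  dev <- aggregate_burden(cells, "development")
  expect_setequal(dev$development, "less developed")  # Alpha/Beta are not developed labels
  bands <- aggregate_burden(cells, "age_band")
  expect_setequal(bands$age_band, "20-49")

  # misaligned draws are refused
  broken <- cells
  broken$draw_2[1] <- NA
  expect_error(aggregate_burden(broken, "sex"), "draw")
})

test_that("age-band collapse follows the 20-49 / 50-69 / 70+ rule", {
  expect_equal(pafburden:::age_band_of(c("20-24", "45-49", "50-54", "65-69",
                                         "70-74", "85+")),
               c("20-49", "20-49", "50-69", "50-69", "70+", "70+"))
})

test_that("development mapping keys on region with country overrides", {
  expect_equal(development_status(c("North America", "South Asia",
                                    "Europe and Central Asia")),
               c("more developed", "less developed", "more developed"))
  expect_equal(development_status("East Asia and Pacific", country = "Japan"),
               "more developed")
  expect_equal(development_status("East Asia and Pacific", country = "China"),
               "less developed")
})

test_that("ASIR matches direct standardization and its invariances", {
  # uniform rates: ASIR equals the common rate regardless of weights
  std2 <- tibble::tibble(age_group = c("20-24", "25-29"),
                         weight = c(0.25, 0.75))
  cells <- tibble::tibble(
    region = "R", sex = "female", disease = "d",
    age_group = c("20-24", "25-29"),
    population = c(1000, 4000),
    draw_1 = c(1, 4)   # rate 0.001 in both bands
  )
  got <- asir(cells, std2)
  expect_equal(got$draw_1, 100, tolerance = 1e-12)

  # worked two-band example: 1e5 * (0.25*0.001 + 0.75*0.003) = 250
  cells2 <- dplyr::mutate(cells, draw_1 = c(1, 12))
  expect_equal(asir(cells2, std2)$draw_1, 250, tolerance = 1e-12)

  # equality with an independently coded direct-standardization oracle
  direct_std <- function(cases, pop, w) sum(w * cases / pop) * 1e5
  set.seed(99)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    std <- tibble::tibble(age_group = paste0("a", 1:k),
                          weight = {w <- runif(k); w / sum(w)})
    cl <- tibble::tibble(region = "R", sex = "m", disease = "d",
                         age_group = paste0("a", 1:k),
                         population = runif(k, 1e3, 1e5),
                         draw_1 = runif(k, 1, 500),
                         draw_2 = runif(k, 1, 500))
    got <- asir(cl, std)
    expect_equal(got$draw_1, direct_std(cl$draw_1, cl$population, std$weight),
                 tolerance = 1e-10)
    expect_equal(got$draw_2, direct_std(cl$draw_2, cl$population, std$weight),
                 tolerance = 1e-10)
  }

  # splitting a band evenly at equal rates leaves ASIR unchanged
  split <- tibble::tibble(
    region = "R", sex = "female", disease = "d",
    age_group = c("20-24a", "20-24b", "25-29"),
    population = c(500, 500, 4000),
    draw_1 = c(0.5, 0.5, 4)
  )
  std_split <- tibble::tibble(age_group = c("20-24a", "20-24b", "25-29"),
                              weight = c(0.125, 0.125, 0.75))
  expect_equal(asir(split, std_split)$draw_1, 100, tolerance = 1e-12)

  # missing band is an error listing the gap
  expect_error(asir(cells[1, ], std2), "25-29")
})

test_that("the WHO standard weights renormalize over adult bands", {
  std <- who_standard_population()
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  expect_equal(std$age_group[1], "20-24")
  expect_true(all(diff(std$weight) < 0))  # weights decline with age
  full <- who_standard_population(age_min = 0)
  expect_equal(nrow(full), 18)
})

test_that("paf_table crosses prevalence with gated relative risks", {
  pe <- tibble::tibble(region = c("R1", "R2"), sex = "female",
                       pe = c(0.1, 0.2), se = 0.01, method = "geographical")
  rr <- tibble::tibble(disease = c("a", "b"), rr = c(1.5, 1.2))
  pafs <- paf_table(pe, rr, gated = "a")
  expect_equal(unique(pafs$disease), "a")
  expect_equal(nrow(pafs), 2)
  expect_equal(pafs$paf, levin_paf(pafs$pe, pafs$rr), tolerance = 1e-15)
})
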