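make_instruments <- function(m, slope, seed = 1, noise = 0.01,
                             disease = "stroke") {
  set.seed(seed)
  bx <- abs(rnorm(m, 0, 0.08)) + 0.04
  so <- runif(m, 0.008, 0.015)
  tibble::tibble(
    disease = disease, direction = "forward",
    variant_id = paste0("v", seq_len(m)),
    beta_exposure = bx, se_exposure = 0.005,
    p_exposure = 1e-10,
    beta_outcome = slope * bx + rnorm(m, 0, noise),
    se_outcome = so
  )
}

test_that("the Wald ratio is beta_outcome/beta_exposure with delta-method SE", {
  v <- tibble::tibble(disease = "d", variant_id = "v1",
                      beta_exposure = 1, se_exposure = 0.01,
                      beta_outcome = -0.2, se_outcome = 0.05)
  w <- wald_ratio(v)
  expect_equal(w$slope, -0.2)
  expect_equal(w$or_per_year, exp(-0.2), tolerance = 1e-12)
  expect_equal(w$se, 0.05)

  v0 <- dplyr::mutate(v, beta_outcome = 0)
  expect_equal(wald_ratio(v0)$or_per_year, 1)

  expect_error(wald_ratio(dplyr::mutate(v, beta_exposure = 0)), "undefined")
})

test_that("delta-method Wald SE matches Monte-Carlo dispersion at small noise", {
  v <- tibble::tibble(disease = "d", variant_id = "v1",
                      beta_exposure = 0.5, se_exposure = 0.001,
                      beta_outcome = -0.1, se_outcome = 0.01)
  analytic <- wald_ratio(v)$se
  set.seed(42)
  mc <- sd(rnorm(20000, v$beta_outcome, v$se_outcome) /
             rnorm(20000, v$beta_exposure, v$se_exposure))
  expect_equal(analytic, mc, tolerance = 0.1)
})

test_that("IVW matches the weighted-least-squares normal equations", {
  # noiseless: exact recovery of the common slope
  clean <- make_instruments(8, slope = -0.15, noise = 0)
  fit <- mr_ivw(clean)
  expect_equal(fit$slope, -0.15, tolerance = 1e-12)
  expect_equal(fit$q, 0, tolerance = 1e-18)

  # 5 noisy variants: zero-intercept WLS oracle via the normal equations
  ins <- make_instruments(5, slope = -0.2, seed = 9)
  w <- 1 / ins$se_outcome^2
  beta_wls <- sum(w * ins$beta_exposure * ins$beta_outcome) /
    sum(w * ins$beta_exposure^2)
  se_wls <- sqrt(1 / sum(w * ins$beta_exposure^2))
  fit <- mr_ivw(ins)
  expect_equal(fit$slope, beta_wls, tolerance = 1e-12)
  expect_equal(fit$se, se_wls, tolerance = 1e-12)

  # single variant degenerates to the Wald ratio
  expect_message(one <- mr_ivw(clean[1, ]), "Wald")
  expect_equal(one$slope, wald_ratio(clean[1, ])$slope)
})

test_that("IVW estimates are equivariant under exposure rescaling", {
  ins <- make_instruments(12, slope = -0.2, seed = 4)
  base <- mr_ivw(ins)$slope
  for (c in c(0.5, 2, 10)) {
    scaled <- dplyr::mutate(ins, beta_exposure = beta_exposure * c)
    expect_equal(mr_ivw(scaled)$slope, base / c, tolerance = 1e-10)
  }
})

test_that("sensitivity estimators behave on clean and contaminated data", {
  clean <- make_instruments(10, slope = -0.2, noise = 0)
  est <- suppressMessages(sensitivity_estimates(clean))
  expect_s3_class(est, "paf_mr")
  expect_setequal(est$method, c("ivw", "egger", "weighted_median"))
  egger <- dplyr::filter(est, method == "egger")
  expect_equal(egger$slope, -0.2, tolerance = 1e-10)
  expect_equal(egger$intercept, 0, tolerance = 1e-10)
  wm <- dplyr::filter(est, method == "weighted_median")
  expect_equal(wm$slope, -0.2, tolerance = 1e-10)

  # equal weights: weighted median equals the ordinary median of ratios
  eq <- tibble::tibble(disease = "d",
                       variant_id = paste0("v", 1:5),
                       beta_exposure = 1, se_exposure = 0.01,
                       beta_outcome = c(-0.3, -0.1, -0.2, -0.25, -0.15),
                       se_outcome = 0.02)
  wm_eq <- mr_weighted_median(eq)
  expect_equal(wm_eq$slope, median(eq$beta_outcome), tolerance = 1e-10)

  # too few variants: Egger omitted with a notice
  expect_message(two <- sensitivity_estimates(clean[1:2, ]), "Egger omitted")
  expect_false("egger" %in% two$method)

  # tidier surface
  gl <- glance(est)
  expect_equal(gl$disease, "stroke")
  expect_true(is.finite(gl$p_egger_intercept))
})

test_that("the weighted median resists directional pleiotropy better than IVW", {
  n_rep <- 200
  hits_wm <- hits_ivw <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ins <- make_instruments(20, slope = -0.2, seed = 1000 + i)
    # directional pleiotropy in half the variants
    ins$beta_outcome[1:10] <- ins$beta_outcome[1:10] + 0.05
    hits_ivw[i] <- abs(mr_ivw(ins)$slope - (-0.2))
    hits_wm[i] <- abs(mr_weighted_median(ins, n_boot = 10, seed = i)$slope - (-0.2))
  }
  expect_gte(mean(hits_wm < hits_ivw), 0.7)
})

test_that("the causal gate admits significant harmful effects only", {
  rows <- tibble::tibble(
    disease = c("harmful", "protective", "null"),
    direction = "forward", method = "ivw",
    n_variants = 20, slope = log(c(0.90, 1.10, 0.99)),
    se = 0.02, or_per_year = c(0.90, 1.10, 0.99),
    ci_low = NA_real_, ci_high = NA_real_,
    p = c(0.001, 0.001, 0.60), q = 1
  )
  gate <- gate_diseases(rows)
  expect_true(gate$causal_gate[gate$disease == "harmful"])
  expect_false(gate$causal_gate[gate$disease == "protective"])
  expect_false(gate$causal_gate[gate$disease == "null"])
})

test_that("direction flipping inverts the OR and swaps the CI", {
  fit <- mr_ivw(make_instruments(10, slope = -0.2, seed = 2))
  flipped <- flip_direction(fit)
  expect_equal(flipped$slope, -fit$slope)
  expect_equal(flipped$or_per_year, 1 / fit$or_per_year, tolerance = 1e-12)
  expect_equal(flipped$ci_low, 1 / fit$ci_high, tolerance = 1e-12)
  expect_equal(flipped$ci_high, 1 / fit$ci_low, tolerance = 1e-12)
})

test_that("instrument selection filters at genome-wide significance", {
  ins <- make_instruments(6, slope = -0.1)
  ins$p_exposure <- c(1e-10, 1e-9, 1e-7, 1e-3, 4.9e-8, 5.1e-8)
  kept <- select_instruments(ins)
  expect_setequal(kept$variant_id, c("v1", "v2", "v5"))
})

test_that("GWAS summary tables round-trip through CSV", {
  ins <- make_instruments(5, slope = -0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    dplyr::select(ins, variant_id, beta_exp = beta_exposure,
                  se_exp = se_exposure, p_exp = p_exposure,
                  beta_out = beta_outcome, se_out = se_outcome), path)
  back <- read_gwas_table(path)
  expect_equal(back$beta_exposure, ins$beta_exposure, tolerance = 1e-10)
  expect_equal(mr_ivw(back)$slope, mr_ivw(ins)$slope, tolerance = 1e-10)
})
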