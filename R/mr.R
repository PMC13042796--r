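## Two-sample Mendelian randomization. Exposure is puberty timing in years
## of delay per allele; outcomes are disease log-odds per allele. The causal
## effect is reported as an OR per 1-year increase (delay) in puberty
## timing: OR < 1 means earlier maturation raises disease risk.

check_instruments <- function(instruments, min_variants = 1) {
  check_columns(instruments,
                c("variant_id", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome"),
                "instrument table")
  if (nrow(instruments) < min_variants) {
    abort(sprintf("need at least %d instrument(s), got %d",
                  min_variants, nrow(instruments)))
  }
  if (anyDuplicated(instruments$variant_id)) abort("variant_ids must be unique")
  if (any(instruments$se_exposure <= 0 | instruments$se_outcome <= 0)) {
    abort("instrument standard errors must be positive")
  }
  invisible(instruments)
}

mr_row <- function(instruments, method, slope, se, q = NA_real_) {
  disease <- if ("disease" %in% names(instruments)) instruments$disease[1] else NA_character_
  direction <- if ("direction" %in% names(instruments)) instruments$direction[1] else "forward"
  tibble(
    disease = disease, direction = direction, method = method,
    n_variants = nrow(instruments),
    slope = slope, se = se,
    or_per_year = exp(slope),
    ci_low = exp(slope - Z95 * se), ci_high = exp(slope + Z95 * se),
    p = 2 * pnorm(-abs(slope / se)),
    q = q
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' `slope = beta_outcome / beta_exposure`, with first-order delta-method
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param instruments One-row instrument tibble (columns `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`).
#' @return One-row tibble: `method = "wald"`, `slope`, `se`, `or_per_year`
#'   (per 1-year delay in puberty timing), 95% CI and p-value.
#' @export
wald_ratio <- function(instruments) {
  check_instruments(instruments, 1)
  if (nrow(instruments) > 1) abort("wald_ratio() takes a single variant; use mr_ivw() for several")
  if (instruments$beta_exposure == 0) {
    abort("beta_exposure is 0: Wald ratio undefined (null instrument)")
  }
  slope <- instruments$beta_outcome / instruments$beta_exposure
  se <- instruments$se_outcome / abs(instruments$beta_exposure)
  mr_row(instruments, "wald", slope, se)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-variant Wald ratios `r_j = beta_outcome_j / beta_exposure_j`
#' with weights `w_j = beta_exposure_j^2 / se_outcome_j^2` — algebraically a
#' zero-intercept regression of outcome betas on exposure betas weighted by
#' `1/se_outcome^2`. Cochran's Q over the ratios measures instrument
#' heterogeneity. With a single variant the estimate degenerates to the Wald
#' ratio (with a notice).
#'
#' @param instruments Instrument tibble, one row per independent variant.
#' @return One-row tibble as [wald_ratio()], `method = "ivw"`, plus `q`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' mr_ivw(simulate_instruments(cfg, "depression"))
#' @export
mr_ivw <- function(instruments) {
  check_instruments(instruments, 1)
  if (nrow(instruments) < 2) {
    inform("mr_ivw(): single variant; falling back to the Wald ratio")
    out <- wald_ratio(instruments)
    out$method <- "ivw"
    out$q <- 0
    return(out)
  }
  if (any(instruments$beta_exposure == 0)) abort("beta_exposure of 0 among instruments")
  r <- instruments$beta_outcome / instruments$beta_exposure
  w <- instruments$beta_exposure^2 / instruments$se_outcome^2
  slope <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (r - slope)^2)
  mr_row(instruments, "ivw", slope, se, q)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_outcome^2`), after orienting all exposure betas
#' positive. The slope is the causal estimate; a nonzero intercept signals
#' directional pleiotropy.
#'
#' @param instruments Instrument tibble with at least 3 variants.
#' @return One-row tibble, `method = "egger"`, with additional columns
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments) {
  check_instruments(instruments, 3)
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  # multiplicative random-effects scaling: lm SEs are rescaled so residual
  # under-dispersion (sigma < 1) never shrinks them below the fixed-effect ones
  sigma <- summary(fit)$sigma
  adj <- if (sigma > 0) max(1, sigma) / sigma else 1
  out <- mr_row(instruments, "egger", sm["bx", 1], sm["bx", 2] * adj)
  out$intercept <- sm["(Intercept)", 1]
  out$intercept_se <- sm["(Intercept)", 2] * adj
  out$intercept_p <- 2 * pnorm(-abs(out$intercept / out$intercept_se))
  out
}

#' Weighted-median causal estimate
#'
#' The weighted median of per-variant Wald ratios under inverse-variance
#' weights: consistent when at least half the total weight comes from valid
#' instruments (50% breakdown point). The standard error is a parametric
#' bootstrap.
#'
#' @param instruments Instrument tibble with at least 2 variants.
#' @param n_boot Bootstrap iterations for the SE.
#' @param seed Seed for the bootstrap (deterministic output).
#' @return One-row tibble, `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 200, seed = 1) {
  check_instruments(instruments, 2)
  ratio_w <- function(bx, by, so) {
    r <- by / bx
    w <- bx^2 / so^2
    weighted_median(r, w)
  }
  est <- ratio_w(instruments$beta_exposure, instruments$beta_outcome,
                 instruments$se_outcome)
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(instruments), instruments$beta_exposure, instruments$se_exposure)
    by <- rnorm(nrow(instruments), instruments$beta_outcome, instruments$se_outcome)
    ratio_w(bx, by, instruments$se_outcome)
  }, numeric(1))
  mr_row(instruments, "weighted_median", est, sd(boots))
}

# weighted median with linear interpolation of the cumulative weight
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' IVW plus sensitivity estimators for one instrument set
#'
#' Returns the inverse-variance-weighted estimate alongside MR-Egger and the
#' weighted median. Methods whose minimum variant count is not met are
#' omitted with a notice.
#'
#' @inheritParams mr_ivw
#' @param seed Seed for the weighted-median bootstrap.
#' @return A `paf_mr` tibble, one row per method.
#' @export
sensitivity_estimates <- function(instruments, seed = 1) {
  out <- list(mr_ivw(instruments))
  if (nrow(instruments) >= 3) {
    out <- c(out, list(mr_egger(instruments)))
  } else {
    inform("sensitivity_estimates(): < 3 variants, MR-Egger omitted")
  }
  if (nrow(instruments) >= 2) {
    out <- c(out, list(mr_weighted_median(instruments, seed = seed)))
  } else {
    inform("sensitivity_estimates(): < 2 variants, weighted median omitted")
  }
  out <- bind_rows(out)
  class(out) <- c("paf_mr", class(out))
  out
}

#' Filter instruments at genome-wide significance
#'
#' Keeps variants with `p_exposure < threshold` (default 5e-8). Instruments
#' are assumed LD-independent.
#'
#' @param instruments Instrument tibble with a `p_exposure` column.
#' @param threshold Exposure p-value cut-off.
#' @return Filtered tibble.
#' @export
select_instruments <- function(instruments, threshold = 5e-8) {
  check_columns(instruments, "p_exposure", "instrument table")
  filter(instruments, .data$p_exposure < threshold)
}

#' Flip the effect-direction convention
#'
#' Converts an MR result between "per 1-year delay" and "per 1-year earlier"
#' puberty timing by negating the slope and reciprocating the OR and CI.
#'
#' @param result MR result tibble (rows from [mr_ivw()] and friends).
#' @return The result with the opposite sign convention.
#' @export
flip_direction <- function(result) {
  result %>% mutate(
    slope = -.data$slope,
    or_per_year = exp(.data$slope),
    ci_low2 = 1 / .data$ci_high, ci_high = 1 / .data$ci_low,
    ci_low = .data$ci_low2
  ) %>% select(-"ci_low2")
}

#' Decide which diseases pass the causal gate
#'
#' A disease enters the burden calculation when its forward IVW estimate is
#' significant (p < `alpha`) with OR per year of delay below 1 (delay
#' protective, hence early maturation harmful). Reverse-direction results
#' are carried through for reporting but do not veto.
#'
#' @param results MR result tibble covering one `method = "ivw"`,
#'   `direction = "forward"` row per disease (other rows are ignored for the
#'   decision).
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble with one row per disease: `disease`, `or_per_year`, `p`,
#'   `causal_gate` (logical). Gated-in diseases are
#'   `dplyr::filter(out, causal_gate)$disease`.
#' @export
gate_diseases <- function(results, alpha = 0.05) {
  fwd <- filter(results, .data$method == "ivw", .data$direction == "forward")
  if (nrow(fwd) == 0) abort("gate_diseases(): no forward IVW results found")
  fwd %>%
    select("disease", "or_per_year", "p") %>%
    mutate(causal_gate = .data$p < alpha & .data$or_per_year < 1) %>%
    arrange(.data$disease)
}

#' Read a two-sample GWAS summary table from CSV
#'
#' Expects columns `variant_id`, `beta_exp`, `se_exp`, `p_exp`, `beta_out`,
#' `se_out` (an optional `disease` column is carried through).
#'
#' @param path Path to the CSV file.
#' @return Instrument tibble ready for [mr_ivw()].
#' @export
read_gwas_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("variant_id", "beta_exp", "se_exp", "p_exp",
                     "beta_out", "se_out"), "GWAS CSV")
  x %>% rename(beta_exposure = "beta_exp", se_exposure = "se_exp",
               p_exposure = "p_exp", beta_outcome = "beta_out",
               se_outcome = "se_out")
}
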