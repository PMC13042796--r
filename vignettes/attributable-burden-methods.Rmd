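---
title: "Methods: estimating disease burden attributable to early maturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating disease burden attributable to early maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafburden)
library(dplyr)
```

## The estimation chain

`pafburden` estimates how many incident disease cases in a population are
attributable to early maturation (puberty onset earlier than the reference
population: menarche before age 12, or 13 in Asian populations; voice break
earlier than the population average). The chain has five stages, each a
module of the package:

1. **Relative risks** (`pool_effects()`): epidemiological effect estimates
   (OR, RR, HR — treated as interchangeable ratio measures on the log
   scale) are pooled per disease with inverse-variance weights. The model is
   chosen by the heterogeneity rule: fixed effect when $I^2 < 50$,
   DerSimonian–Laird random effects otherwise, where
   $I^2 = \max\{0, 100\,(Q - (k-1))/Q\}$ from Cochran's $Q$ under
   fixed-effect weights and
   $\hat\tau^2 = \max\{0,\,(Q - (k-1)) / (\sum w - \sum w^2 / \sum w)\}$.
2. **Causal gate** (`mr_ivw()`, `gate_diseases()`): two-sample Mendelian
   randomization decides which diseases enter the burden calculation.
   Genetic variants associated with puberty timing serve as instruments;
   the inverse-variance-weighted estimate combines per-variant Wald ratios
   $r_j = \beta_{Y,j}/\beta_{X,j}$ with weights
   $w_j = \beta_{X,j}^2/\mathrm{se}_{Y,j}^2$. Effects are expressed as an
   OR per 1-year *increase* (delay) in puberty timing, so OR < 1 means
   early maturation is harmful. A disease is gated in when its forward IVW
   p-value is below 0.05 with OR < 1. Reverse-direction estimates are
   reported but do not veto — no veto rule is part of the gate's
   definition. MR-Egger and the weighted median (`sensitivity_estimates()`)
   are advisory: the field-standard sensitivity pair, chosen here because
   they bracket the two main failure modes (directional pleiotropy;
   a minority of invalid instruments).
3. **Exposure prevalence** (`pool_prevalence()`): three tiers. Surveys
   within a country pool by inverse variance with binomial standard errors
   $\sqrt{p(1-p)/n}$; countries pool into regions by a weighted average
   whose weights are survey sample size times the country's disease case
   count; regions with no surveys at all get a prevalence predicted by an
   ordinary least-squares regression of known regional prevalences on
   regional disease incidence, truncated to $[0,1]$.
4. **Attribution** (`levin_paf()`, `attributable_cases()`, `asir()`):
   Levin's formula
   $\mathrm{PAF} = P_e(\mathrm{RR}-1)\,/\,(P_e(\mathrm{RR}-1)+1)$
   converts prevalence and relative risk into the attributable fraction;
   attributable cases are incidence times PAF, and age-standardized
   incidence rates (per 100,000 person-years) use the WHO World Standard
   population renormalized over ages $\ge 20$.
5. **Uncertainty** (`summarize_ui()`, `aggregate_burden()`): every
   incidence estimate carries Monte-Carlo draws; all arithmetic is applied
   within a draw index, and 95% uncertainty intervals are the 2.5th–97.5th
   draw percentiles, taken only at reporting time.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` (gate) | 0.05 | significance threshold for the causal gate |
| $I^2$ threshold | 50 (strict `<`) | percent; fixed- vs random-effects switch |
| `n_draws` | 1000 | Monte-Carlo draws per incidence estimate |
| `draw_cv` | 0.12 | coefficient of variation of draw noise |
| z for 95% intervals | 1.959964 | two-sided normal quantile, used everywhere |
| instrument p filter | $5\times10^{-8}$ | genome-wide significance, when filtering is requested |
| age bands | 20–24 … 85+ | 5-year bands; reports collapse to 20–49 / 50–69 / 70+ |
| prevalence lag | 20 years | metadata tag linking exposure window to outcome year; not a computation |

PAFs are computed at region × sex level and applied uniformly across age:
age variation enters through the incidence itself, because age-varying
prevalence is normally unavailable. `paf_table()` accepts any prevalence
table, so age-specific $P_e$ can be supplied where it exists.

## The synthetic world

The generator (`sim_config()`, `simulate_*()`) emulates the four input
streams with known ground truth: per-disease true relative risks,
true causal slopes (log-OR per year of pubertal delay, in the
5–19% per-year risk-reduction range reported for these outcomes),
per-country true prevalences (female baseline 0.18, male 0.12, spread ±30%
across countries), and stratified incidence whose observed estimate is one
log-normal realization around the truth, with mean-preserving log-normal
draws around that estimate. The draw family is a modelling choice — the
posterior family of burden-study draws is not published — and log-normal
guarantees positive counts. Because the observed estimate is itself noisy,
the 95% draw interval has honest (~95%) coverage of the true count; had
draws been centered on the truth, coverage would be near 100% and the
uncertainty machinery untestable.

Instrument strength defaults (exposure effects 0.04–0.25 years/allele,
outcome SEs ~0.01) match biobank-scale GWAS and give the IVW estimator
per-disease power above 95% at the smallest default slope; sample sizes
for prevalence surveys (2,000–20,000) are typical of national cohort
studies. One region (by default the last, mirroring the region that lacks
surveys in practice) is generated survey-free so the regression-imputation
path always runs. A single global seed is threaded to every generator
through deterministic substreams; identical configurations are
byte-identical in output.

What the generator does *not* emulate: real-world magnitudes of incidence,
allele frequencies or LD between variants, secular trends in puberty
timing, age-varying prevalence, or regionally varying relative risks.
Passing tests therefore demonstrate the estimation chain's correctness and
calibration, not the field accuracy of any published figure.

## Numerical choices

- Percentiles use linear interpolation between closest order statistics
  (`stats::quantile()` type 7), the most common convention.
- CI ↔ SE conversion on the log scale uses
  $(\log \mathrm{hi} - \log \mathrm{lo}) / (2 \times 1.959964)$.
- Surveys reporting prevalence of exactly 0 or 1 get an
  Agresti–Coull-style $+2/+4$ shift before the binomial SE, keeping their
  inverse-variance weight finite.
- Risk-based prevalence predictions outside $[0,1]$ truncate with a
  warning.
- Protective relative risks (RR < 1) are refused by `levin_paf()` rather
  than producing negative fractions: the gate admits only harmful
  associations, and a protective-exposure stratum reaching the PAF stage
  indicates an upstream error.
- The MR-Egger standard errors are rescaled so residual under-dispersion
  never shrinks them below their fixed-effect counterparts
  (multiplicative random-effects convention).
- Reports round cases (in thousands) to one decimal at the report layer
  only; all internal arithmetic is unrounded. Aggregation is draw-wise and
  exactly additive in any grouping order.
- The reporting age bands collapse 5-year bands as 20–49 / 50–69 / 70+;
  the boundary at 50 is assigned to the middle band.

## Design choices made where the design was open

- **Three sensitivity estimators, IVW primary.** The gate keys on IVW
  alone; Egger and weighted median inform but never decide. This keeps the
  gate's operating characteristics analyzable (its false-positive rate per
  null disease is $\alpha/2$, since significance and direction must agree).
- **Risk-based pooling predictor.** The regression of prevalence on
  incidence uses the all-cause regional incidence rate as the single
  predictor by default; a per-disease predictor is a switch away
  (`pool_risk_based()` takes any named incidence vector). The published
  description does not pin the aggregation level.
- **Geographical pooling weight.** Sample size × case count, with the case
  count left to the caller (all-cause or per-disease), for the same
  reason.
- **Development dichotomy** keys on region with country overrides (Japan,
  Australia, New Zealand), following the WESP developed-economy grouping.
- **WHO standard vintage** is the 2000–2025 World Standard; the standard's
  weights are embedded in code and renormalized over the adult bands
  present in the data being standardized.

## Known limitations

- Under mild between-study heterogeneity (e.g. $\tau = 0.1$) the
  $I^2$-gated rule frequently selects the fixed-effect model, whose CI
  ignores $\tau$; coverage of the pooled CI then falls below nominal.
  This is a property of the published pooling rule, not of its
  implementation; the package's recovery tests use the random-effects CI,
  which carries the between-study spread.
- OR, RR and HR are pooled jointly without rare-disease correction, and a
  single pooled RR per disease is applied worldwide.
- The weighted-median SE is a parametric bootstrap (deterministic under a
  seed), not an analytic formula.
- Real-data preprocessing for MR (allele harmonization, LD clumping,
  Steiger filtering) is out of scope; instruments are assumed independent
  and correctly oriented.

## Problem sizes used in the test-suite

The suite checks statistical calibration at sizes chosen to make binomial
noise on an observed coverage rate small relative to the tolerance bands:
200 replicates for meta-analytic coverage (k = 20 studies), 500 replicates
for IVW coverage (30 instruments), 400 replicates for the 10-disease gate
panel (60 instruments per disease), and 300 replicates at 500 draws for
the uncertainty-interval coverage of total attributable cases, run on a
compact two-region world. The acceptance script runs the full default
world (7 regions × 2 countries, 7 diseases, 14 age bands, 500 draws).

## A worked run

```{r pipeline}
cfg <- sim_config(seed = 7, n_draws = 200)
res <- run_pipeline(cfg)
res$gate
tidy(res$pooled_rr)
res$report$by_region
res$report$overall_paf
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(res$pooled_rr)
plot_burden(res$report)
```
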