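## WHO World Standard population (2000-2025), 5-year bands. Stored as the
## published percentage weights; renormalized over the requested adult age
## range before use.

who_std_weights <- c(
  "0-4"   = 8.86, "5-9"   = 8.69, "10-14" = 8.60, "15-19" = 8.47,
  "20-24" = 8.22, "25-29" = 7.93, "30-34" = 7.61, "35-39" = 7.15,
  "40-44" = 6.59, "45-49" = 6.04, "50-54" = 5.37, "55-59" = 4.55,
  "60-64" = 3.72, "65-69" = 2.96, "70-74" = 2.21, "75-79" = 1.52,
  "80-84" = 0.91, "85+"   = 0.64
)

#' WHO world standard population weights
#'
#' Returns the WHO World Standard (2000-2025) age weights in 5-year bands,
#' restricted to ages at or above `age_min` and renormalized to sum to 1
#' over the retained bands — the weight set used for age-standardizing adult
#' incidence rates.
#'
#' @param age_min Lower age bound (years); bands starting below it are
#'   dropped. Default 20 (adult burden).
#' @return Tibble with columns `age_group`, `weight` (summing to 1).
#' @examples
#' who_standard_population()
#' @export
who_standard_population <- function(age_min = 20) {
  starts <- as.integer(sub("[-+].*$", "", names(who_std_weights)))
  keep <- starts >= age_min
  w <- who_std_weights[keep]
  tibble(age_group = names(w), weight = as.numeric(w) / sum(w))
}

#' Classify countries or regions by development status
#'
#' The dichotomy follows the UN WESP grouping: countries in Europe and North
#' America plus Australia, New Zealand and Japan are "more developed";
#' everything else is "less developed". With only region labels available,
#' the regions "North America" and "Europe and Central Asia" map to more
#' developed; country labels (e.g. Japan) override their region.
#'
#' @param region Character vector of region labels.
#' @param country Optional character vector of country labels (overrides).
#' @return Character vector: `"more developed"` or `"less developed"`.
#' @export
development_status <- function(region, country = NULL) {
  developed_regions <- c("North America", "Europe and Central Asia")
  developed_countries <- c("Japan", "Australia", "New Zealand")
  out <- ifelse(region %in% developed_regions, "more developed", "less developed")
  if (!is.null(country)) {
    out[country %in% developed_countries] <- "more developed"
  }
  out
}
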