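#' Read an incidence table in the GBD results-tool export dialect
#'
#' Accepts the standard export columns `measure_name`, `location_name`,
#' `sex_name`, `age_name`, `cause_name`, `metric_name`, `year`, `val`,
#' `upper`, `lower`, plus optionally `population` and draw-level columns
#' `draw_0..draw_{N-1}`. Incidence rows in Number metric are kept. Draw
#' columns are renamed to the package convention `draw_1..draw_N`; when the
#' export carries no draws, `val` becomes a single degenerate draw.
#'
#' @param path Path to the CSV export.
#' @param region_of Optional named vector mapping `location_name` to a
#'   region label; defaults to using the location as its own region.
#' @return Incidence tibble with columns `region`, `country`, `sex`,
#'   `age_group`, `disease`, `population` (if present) and `draw_*`.
#' @export
read_incidence_gbd <- function(path, region_of = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(x, c("measure_name", "location_name", "sex_name", "age_name",
                     "cause_name", "metric_name", "val"), "GBD export CSV")
  x <- x %>%
    filter(tolower(.data$measure_name) == "incidence",
           tolower(.data$metric_name) == "number")
  old_draws <- grep("^draw_[0-9]+$", names(x), value = TRUE)
  if (length(old_draws) > 0) {
    idx <- as.integer(sub("^draw_", "", old_draws))
    if (min(idx) == 0) {
      names(x)[match(old_draws, names(x))] <- paste0("draw_", idx + 1L)
    }
  } else {
    x$draw_1 <- x$val
  }
  out <- x %>%
    mutate(
      country = .data$location_name,
      region = if (is.null(region_of)) .data$location_name
               else unname(region_of[.data$location_name]),
      sex = tolower(.data$sex_name),
      age_group = standardize_age_label(.data$age_name),
      disease = .data$cause_name
    )
  keep <- c("region", "country", "sex", "age_group", "disease",
            intersect("population", names(out)), draw_cols(out))
  out[keep]
}

# "20 to 24" / "20-24 years" / "85 plus" -> "20-24" / "85+"
standardize_age_label <- function(age) {
  a <- tolower(trimws(age))
  a <- sub("\\s*years?$", "", a)
  a <- sub("\\s+to\\s+", "-", a)
  a <- sub("\\s*(plus|\\+)$", "+", a)
  a <- sub("^(\\d+)\\+$", "\\1+", a)
  gsub("\\s", "", a)
}

#' Published global attributable-burden table for early maturation, 2021
#'
#' Cell values of the published stratified tables of incident cases
#' attributable to early maturation in adults (>= 20 years) in 2021: cases
#' in thousands with 95% UIs by sex and disease, by development status and
#' broad age band, and by geographic region (with country call-outs), plus
#' PAF (%) and ASIR (per 100,000 person-years) where printed. Used as input
#' data for aggregation-identity checks: marginal rows in the source are
#' reproducible by summing the component cells.
#'
#' @return Tibble with columns `dimension` (sex / development / age_band /
#'   region / country / world), `disease`, `stratum`, `cases_thousands`,
#'   `ui_low`, `ui_high`, `paf_percent`, `asir`, `asir_low`, `asir_high`.
#' @export
global_burden_2021 <- function() {
  readr::read_csv(
    system.file("extdata", "global_burden_2021.csv", package = "pafburden"),
    show_col_types = FALSE)
}
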