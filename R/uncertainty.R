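#' Summarize Monte-Carlo draws into a point estimate and 95% UI
#'
#' The point estimate is the mean of the draws; the uncertainty interval is
#' the 2.5th–97.5th percentile computed with linear interpolation between
#' closest order statistics (the default `stats::quantile()` type 7).
#'
#' @param draws Numeric vector of draws (length >= 1).
#' @return A one-row tibble with columns `point`, `ui_low`, `ui_high`.
#' @examples
#' summarize_ui(rlnorm(1000))
#' @export
summarize_ui <- function(draws) {
  if (length(draws) == 0 || all(is.na(draws))) {
    abort("summarize_ui(): no draws supplied")
  }
  if (length(draws) == 1) {
    warn("summarize_ui(): a single draw; UI collapses to the point estimate")
    return(tibble(point = draws, ui_low = draws, ui_high = draws))
  }
  q <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  tibble(point = mean(draws), ui_low = q[1], ui_high = q[2])
}

#' Collapse draw columns of a table into point and UI columns
#'
#' Applies [summarize_ui()] row-wise to the `draw_*` columns and replaces
#' them with `point`, `ui_low`, `ui_high`. All other columns pass through.
#'
#' @param x A data frame with `draw_*` columns.
#' @param prefix Optional prefix for the three summary columns.
#' @return A tibble without draw columns.
#' @export
summarize_draws <- function(x, prefix = "") {
  dc <- draw_cols(x)
  if (length(dc) == 0) abort("summarize_draws(): no draw_* columns found")
  m <- as.matrix(x[dc])
  lo <- apply(m, 1, quantile, probs = 0.025, names = FALSE, type = 7)
  hi <- apply(m, 1, quantile, probs = 0.975, names = FALSE, type = 7)
  out <- x[setdiff(names(x), dc)]
  out[[paste0(prefix, "point")]] <- rowMeans(m)
  out[[paste0(prefix, "ui_low")]] <- lo
  out[[paste0(prefix, "ui_high")]] <- hi
  as_tibble(out)
}

#' Apply a function draw-wise across aligned draw vectors
#'
#' Runs `f` once per draw index, passing the k-th element of every draw
#' vector in `...`, so that uncertainty propagates through arbitrary stages
#' without ever mixing draws. All inputs must share the same number of
#' draws; scalars are recycled.
#'
#' @param f Function of as many arguments as there are inputs.
#' @param ... Numeric vectors (draw vectors) and/or scalars.
#' @return Numeric vector of length `n_draws` with the per-draw results.
#' @examples
#' propagate(`+`, c(1, 2, 3), c(10, 20, 30))
#' @export
propagate <- function(f, ...) {
  inputs <- list(...)
  lens <- vapply(inputs, length, integer(1))
  nd <- unique(lens[lens > 1])
  if (length(nd) > 1) {
    abort(sprintf("propagate(): misaligned draw counts: %s",
                  paste(nd, collapse = ", ")))
  }
  nd <- if (length(nd) == 0) 1L else nd
  if (nd == 1) warn("propagate(): single draw; UI will collapse to the point estimate")
  vapply(seq_len(nd), function(k) {
    args <- lapply(inputs, function(v) if (length(v) == 1) v else v[[k]])
    as.numeric(do.call(f, args))
  }, numeric(1))
}

#' Sample parameter draws for a pooled relative risk or prevalence
#'
#' Draws are normal on the log scale for ratio measures and on the logit
#' scale for proportions, then back-transformed, so ratio draws stay
#' positive and prevalence draws stay inside (0, 1). Used when relative-risk
#' or prevalence uncertainty is propagated into the attributable fraction
#' (off by default in [run_pipeline()], where uncertainty enters through the
#' incidence draws).
#'
#' @param estimate Point estimate (a ratio > 0, or a proportion in (0,1)).
#' @param se Standard error on the transformed scale (log or logit).
#' @param n_draws Number of draws.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param scale `"log"` for ratio measures, `"logit"` for proportions.
#' @return Numeric vector of `n_draws` draws on the natural scale.
#' @export
sample_parameter_draws <- function(estimate, se, n_draws, seed,
                                   scale = c("log", "logit")) {
  scale <- match.arg(scale)
  stopifnot(se >= 0, n_draws >= 1)
  set.seed(as.integer(seed))
  z <- rnorm(n_draws, 0, se)
  if (scale == "log") {
    stopifnot(estimate > 0)
    exp(log(estimate) + z)
  } else {
    stopifnot(estimate > 0, estimate < 1)
    stats::plogis(stats::qlogis(estimate) + z)
  }
}
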