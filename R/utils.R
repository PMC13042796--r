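#' Names of the Monte-Carlo draw columns in a table
#'
#' Draw-level quantities are stored wide, one column per draw, named
#' `draw_1 ... draw_n`. Draw index k is a coherent scenario: summing cells
#' within column k is valid before any percentile is taken.
#'
#' @param x A data frame possibly carrying draw columns.
#' @return Character vector of draw column names, in draw order.
#' @export
draw_cols <- function(x) {
  nm <- grep("^draw_[0-9]+$", names(x), value = TRUE)
  nm[order(as.integer(sub("^draw_", "", nm)))]
}

#' Number of draws carried by a table
#' @param x A data frame with `draw_*` columns.
#' @return Integer count of draw columns.
#' @export
n_draws <- function(x) length(draw_cols(x))

# stop unless all listed columns are present
check_columns <- function(x, cols, what = "input") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# derive a deterministic 32-bit substream seed from a base seed and a label,
# so each generator draws from its own stream under one global seed
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 100003L)
}
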