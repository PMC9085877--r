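#' Pearson correlation between current ratios and a target profile
#'
#' Both vectors are normalised to sum 1 before the correlation, so any
#' scale of weights can be compared. By default the correlation is taken
#' in linear space; `log_space = TRUE` correlates `log10(ratio + offset)`
#' instead (the dot-plot convention for heavy-tailed profiles).
#'
#' @param current Non-negative current ratios (probability vector or
#'   weights).
#' @param target Non-negative target weights, same length.
#' @param log_space Correlate on the log scale (default `FALSE`).
#' @param offset Additive offset before the log (default 1e-6).
#' @return Pearson r in `[-1, 1]`, or `NA` when either vector has zero
#'   variance.
#' @export
ratio_correlation <- function(current, target, log_space = FALSE, offset = 1e-6) {
  stopifnot(length(current) == length(target), sum(target) > 0)
  cur <- if (sum(current) > 0) current / sum(current) else current
  tar <- target / sum(target)
  if (log_space) {
    cur <- log10(cur + offset)
    tar <- log10(tar + offset)
  }
  if (stats::sd(cur) == 0 || stats::sd(tar) == 0) return(NA_real_)
  cor(cur, tar)
}

#' Summarise replicate results
#'
#' Order statistics of a set of per-seed outcomes, matching the
#' box-and-whisker reporting of replicate runs.
#'
#' @param values Numeric vector (one value per replicate seed).
#' @return Named numeric vector: `median`, `q1`, `q3`, `iqr`, `min`,
#'   `max`, `n`.
#' @export
replicate_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  c(median = median(values, na.rm = TRUE), q1 = q[1], q3 = q[2],
    iqr = q[2] - q[1], min = min(values, na.rm = TRUE),
    max = max(values, na.rm = TRUE), n = length(values))
}
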