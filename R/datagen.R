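#' Generate a synthetic target profile
#'
#' Profiles emulate the target inputs of the learning experiments:
#' \describe{
#'   \item{`linear`}{weights `1, 2, ..., n` in leaf order.}
#'   \item{`shuffled_linear`}{a random permutation of `1..n`.}
#'   \item{`lognormal`}{`exp(N(0, sigma^2))` draws, emulating the
#'     heavy-tailed magnitude spread of RNA-seq expression profiles.}
#' }
#'
#' @param n Number of factors (>= 2).
#' @param kind One of `"linear"`, `"shuffled_linear"`, `"lognormal"`.
#' @param sigma Log-scale standard deviation for `"lognormal"`
#'   (default 1.5).
#' @param seed Optional seed making the draw reproducible without
#'   touching the caller's RNG stream.
#' @return Numeric weight vector of length `n`.
#' @examples
#' synth_targets(64, "linear")[1:5]
#' @export
synth_targets <- function(n, kind = c("linear", "shuffled_linear", "lognormal"),
                          sigma = 1.5, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 2, sigma >= 0)
  with_seed(seed, {
    switch(kind,
      linear = as.numeric(seq_len(n)),
      shuffled_linear = as.numeric(sample.int(n)),
      lognormal = exp(rnorm(n, 0, sigma)))
  })
}

#' Generate a correlated initial/target profile pair
#'
#' Draws two log-normal profiles whose Pearson correlation (on the linear
#' scale) is tuned to `correlation` by mixing a shared and an independent
#' log-scale component. For bivariate log-normals with common log-sd
#' `sigma` and log-scale correlation `rho`, the linear-scale Pearson
#' correlation is `(exp(rho * sigma^2) - 1) / (exp(sigma^2) - 1)`;
#' inverting this gives the mixture weight. `correlation = 1` yields
#' identical profiles, `correlation = 0` independent ones (the
#' independent-shuffle control).
#'
#' @param n Number of factors.
#' @param correlation Desired linear-scale Pearson correlation in
#'   `[0, 1]`.
#' @param sigma Log-scale standard deviation (default 1.5).
#' @param seed Optional seed.
#' @return A list with elements `initial` and `target` (weight vectors).
#' @export
synth_paired_profiles <- function(n, correlation, sigma = 1.5, seed = NULL) {
  stopifnot(n >= 2, correlation >= 0, correlation <= 1, sigma > 0)
  with_seed(seed, {
    ev <- expm1(sigma^2)
    rho <- log1p(correlation * ev) / sigma^2
    rho <- min(max(rho, 0), 1)
    a <- sigma * sqrt(rho)
    b <- sigma * sqrt(1 - rho)
    shared <- rnorm(n)
    list(initial = exp(a * shared + b * rnorm(n)),
         target = exp(a * shared + b * rnorm(n)))
  })
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Normalise a profile to a fixed total
#'
#' Scales weights so they sum to `total` (1e6 mirrors TPM-style
#' normalisation of expression ratios). Pair targets are scale-invariant,
#' so normalisation never changes the learned ratios.
#'
#' @param weights Non-negative weights (some positive).
#' @param total Target sum (default 1e6).
#' @return Scaled weights.
#' @export
normalize_profile <- function(weights, total = 1e6) {
  s <- sum(weights)
  if (s <= 0) stop("cannot normalise an all-zero profile")
  if (any(weights < 0)) stop("weights must be non-negative")
  weights * (total / s)
}

#' Read a genes x cells expression table
#'
#' Expects a TSV or CSV file whose first column holds gene names and
#' whose header row holds cell labels; the body must be numeric and
#' non-negative. Duplicate gene names are summed into one row with a
#' warning (the gene symbol is the unit of the architecture).
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @return Numeric matrix with gene row names and cell column names.
#' @export
read_expression_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a gene-name column plus at least one cell column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")  # non-numeric -> NA, caught below
  if (anyNA(m)) stop("expression table contains missing or non-numeric values")
  if (any(m < 0)) stop("expression table contains negative values")
  if (anyDuplicated(genes)) {
    warning("duplicate gene names summed into single rows")
    m <- rowsum(m, group = genes, reorder = FALSE)
  } else {
    rownames(m) <- genes
  }
  m
}

#' Filter genes by an expression threshold
#'
#' Keeps the rows whose maximum over the designated cells strictly
#' exceeds `threshold` ("expressed at more than `threshold`" in at least
#' one of them). With `cells = NULL` all columns are considered; pass a
#' subset of columns to apply the rule per condition. Idempotent. An
#' empty result is returned (with a warning), not an error.
#'
#' @param matrix Genes x cells expression matrix.
#' @param threshold Strict lower bound.
#' @param cells Optional column indices or names defining the rule's
#'   scope.
#' @return The filtered matrix.
#' @export
filter_genes <- function(matrix, threshold, cells = NULL) {
  stopifnot(is.matrix(matrix), threshold >= 0)
  sub <- if (is.null(cells)) matrix else matrix[, cells, drop = FALSE]
  keep <- apply(sub, 1, max) > threshold
  if (!any(keep)) warning("no genes pass the expression threshold")
  matrix[keep, , drop = FALSE]
}
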