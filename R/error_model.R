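#' Mean squared error between current and target pair ratios
#'
#' The decay probability of a learning pair is driven by the squared
#' difference between the current A-fraction `x_A / (x_A + x_B)` and the
#' target A-fraction `T_A / (T_A + T_B)`. The value is identical whether
#' computed on the A side or the B side of the pair.
#'
#' When the pair is empty (`x_A + x_B == 0`) the current fraction is read
#' as 1/2: an empty pair carries no ratio information and 1/2 is the
#' symmetric prior.
#'
#' @param x_A,x_B Non-negative current branch values.
#' @param T_A,T_B Non-negative target weights; their sum must be positive.
#' @return A single numeric in `[0, 1]`.
#' @examples
#' pair_mse(1, 2, 1, 2)   # 0: current equals target
#' pair_mse(1, 1, 1, 2)   # (1/2 - 1/3)^2
#' @export
pair_mse <- function(x_A, x_B, T_A, T_B) {
  stopifnot(x_A >= 0, x_B >= 0, T_A >= 0, T_B >= 0)
  if (T_A + T_B <= 0) {
    stop("undefined target: T_A + T_B must be positive")
  }
  cur <- if (x_A + x_B > 0) x_A / (x_A + x_B) else 0.5
  (cur - T_A / (T_A + T_B))^2
}

#' Approximate an error value to a decay probability level
#'
#' Reduces a raw mean squared error to the probability level actually used
#' for decay. Three modes are supported:
#' \describe{
#'   \item{`exact`}{the value is used unchanged.}
#'   \item{`stepwise`}{the value is expressed in base-10 exponential
#'     notation, the mantissa is reduced to 1 and only the exponent kept,
#'     giving a level in `{10^-1, 10^-2, 10^-3, ...}`; values of 1 or more
#'     are capped at `10^-1`, and an exact zero stays zero (the stepwise
#'     level may become unlimitedly small).}
#'   \item{`k_step`}{the stepwise level clamped from below at `10^-k`, so
#'     only `k` levels `10^-1 ... 10^-k` are possible. The lower clamp
#'     applies even when the error is exactly zero, so turnover never
#'     ceases.}
#' }
#'
#' By default the mantissa is truncated (`10^floor(log10(m))`), so the
#' level never exceeds the raw error; `rounding = "half_up"` instead
#' rounds mantissas of 5 or more up to the next level.
#'
#' @param m Error value(s) in `[0, 1]` (vectorised).
#' @param mode One of `"exact"`, `"stepwise"`, `"k_step"`, or a compact
#'   token such as `"step:3"` (equivalent to `mode = "k_step", k = 3`).
#' @param k Number of levels for `k_step` mode (positive integer).
#' @param rounding `"truncate"` (default) or `"half_up"`.
#' @return Numeric vector of approximated error levels.
#' @examples
#' approx_error(0.027778, "stepwise")       # 0.01
#' approx_error(1e-7, "step:3")             # 0.001
#' approx_error(0.5, "stepwise")            # 0.1 (capped)
#' @export
approx_error <- function(m, mode = "exact", k = NULL, rounding = c("truncate", "half_up")) {
  rounding <- match.arg(rounding)
  em <- parse_error_mode(mode, k)
  stopifnot(is.numeric(m), all(m >= 0), all(m <= 1))
  cpp_approx_error(as.numeric(m), em$code, em$k, rounding == "half_up")
}

#' Parse an error-mode token
#'
#' Error modes are expressed in configuration as one token: `"exact"`,
#' `"stepwise"`, or `"step:<k>"` with `k >= 1` (the model comparisons use
#' `k` in 2..6).
#'
#' @param mode Mode name or token.
#' @param k Explicit `k` when `mode = "k_step"`.
#' @return A list with elements `mode` (canonical name), `code` (integer
#'   used by the compiled engine: 0 exact, 1 stepwise, 2 k-step) and `k`.
#' @export
parse_error_mode <- function(mode, k = NULL) {
  stopifnot(is.character(mode), length(mode) == 1L)
  if (grepl("^step:[0-9]+$", mode)) {
    k <- as.integer(sub("^step:", "", mode))
    mode <- "k_step"
  }
  mode <- match.arg(mode, c("exact", "stepwise", "k_step"))
  if (mode == "k_step") {
    if (is.null(k) || is.na(k) || k < 1) {
      stop("k_step error mode requires a positive integer k")
    }
    k <- as.integer(k)
  } else {
    k <- 0L
  }
  list(mode = mode, code = match(mode, c("exact", "stepwise", "k_step")) - 1L, k = k)
}
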