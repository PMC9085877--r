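#' Construct the state of one learning pair
#'
#' A pair holds two non-negative integer branch values and a small
#' additive bias per branch. The bias enters the competitive-amplification
#' selection weights `(x + beta)` and prevents extinction of a branch;
#' `beta = 1` acts as white noise, `beta = 1e-7` approximates pure
#' competition.
#'
#' @param x_A,x_B Non-negative integer branch values.
#' @param beta_A,beta_B Non-negative biases (default 1).
#' @return A list of class `pair_state`.
#' @export
pair_state <- function(x_A = 1, x_B = 1, beta_A = 1, beta_B = 1) {
  stopifnot(x_A >= 0, x_B >= 0, x_A == round(x_A), x_B == round(x_B),
            beta_A >= 0, beta_B >= 0)
  structure(list(x_A = x_A, x_B = x_B, beta_A = beta_A, beta_B = beta_B),
            class = "pair_state")
}

#' Parameters of the learning-pair process
#'
#' @param alpha_inc Probability of entering the increase process at each
#'   repetition (default 0.1).
#' @param alpha_dec Constant coefficient of the decay probability in
#'   `decay_mode = "scaled"`, or the probability of entering the decrease
#'   process in `decay_mode = "gated"` (default 0.1).
#' @param beta Bias added to both selection weights in competitive
#'   amplification (default 1).
#' @param gamma Probability that an increase is additive (uniform 1:1
#'   selection) rather than competitive (default 0).
#' @param error_mode Error approximation token: `"exact"`, `"stepwise"`,
#'   or `"step:<k>"` (see [approx_error()]).
#' @param rounding Mantissa handling for approximated error,
#'   `"truncate"` or `"half_up"`.
#' @param decay_mode `"scaled"`: every repetition each unit survives with
#'   probability `1 - alpha_dec * eps`; `"gated"`: with probability
#'   `alpha_dec` the pair enters decay and each unit survives with
#'   probability `1 - eps`.
#' @param fixed_epsilon Optional constant error overriding the
#'   MSE-dependent value (`NA` = use the pair's MSE).
#' @return A list of class `learning_params`.
#' @export
learning_params <- function(alpha_inc = 0.1, alpha_dec = 0.1, beta = 1, gamma = 0,
                            error_mode = "exact", rounding = c("truncate", "half_up"),
                            decay_mode = c("scaled", "gated"), fixed_epsilon = NA_real_) {
  rounding <- match.arg(rounding)
  decay_mode <- match.arg(decay_mode)
  probs <- c(alpha_inc = alpha_inc, alpha_dec = alpha_dec, gamma = gamma)
  if (any(probs < 0 | probs > 1)) stop("alpha_inc, alpha_dec and gamma must lie in [0, 1]")
  if (beta < 0) stop("beta must be non-negative")
  if (!is.na(fixed_epsilon) && (fixed_epsilon < 0 || fixed_epsilon > 1)) {
    stop("fixed_epsilon must lie in [0, 1]")
  }
  em <- parse_error_mode(error_mode)
  structure(list(alpha_inc = alpha_inc, alpha_dec = alpha_dec, beta = beta,
                 gamma = gamma, error_mode = em$mode, error_code = em$code,
                 k = em$k, rounding = rounding, decay_mode = decay_mode,
                 fixed_epsilon = fixed_epsilon),
            class = "learning_params")
}

#' One increase step of a learning pair
#'
#' With probability `gamma` the step is an additive increase (A or B
#' selected at a 1:1 ratio); otherwise competitive amplification selects A
#' or B at the `(x_A + beta_A):(x_B + beta_B)` ratio. Exactly one branch
#' value grows by 1.
#'
#' @param state A [pair_state()].
#' @param params A [learning_params()].
#' @return The updated `pair_state`.
#' @export
increase_step <- function(state, params = learning_params()) {
  stopifnot(inherits(state, "pair_state"))
  if (params$gamma > 0 && runif(1) < params$gamma) {
    sel_A <- runif(1) < 0.5
  } else {
    wA <- state$x_A + state$beta_A
    wB <- state$x_B + state$beta_B
    if (wA + wB <= 0) stop("zero total selection weight in competitive amplification")
    sel_A <- runif(1) < wA / (wA + wB)
  }
  if (sel_A) state$x_A <- state$x_A + 1 else state$x_B <- state$x_B + 1
  state
}

#' One decrease step of a learning pair
#'
#' In `"scaled"` mode both branch values are replaced by independent
#' binomial draws with per-unit survival `1 - alpha_dec * epsilon`. In
#' `"gated"` mode, with probability `alpha_dec` the pair enters decay and
#' each unit survives with probability `1 - epsilon`; otherwise the state
#' is unchanged. Both branches are gated together.
#'
#' @param state A [pair_state()].
#' @param epsilon Error value in `[0, 1]` used as decay probability.
#' @param params A [learning_params()].
#' @return The updated `pair_state` (values never increase).
#' @export
decay_step <- function(state, epsilon, params = learning_params()) {
  stopifnot(inherits(state, "pair_state"), epsilon >= 0, epsilon <= 1)
  if (epsilon == 0 || params$alpha_dec == 0) return(state)
  if (params$decay_mode == "scaled") {
    p_surv <- 1 - params$alpha_dec * epsilon
    state$x_A <- as.numeric(stats::rbinom(1, state$x_A, p_surv))
    state$x_B <- as.numeric(stats::rbinom(1, state$x_B, p_surv))
  } else if (runif(1) < params$alpha_dec) {
    p_surv <- 1 - epsilon
    state$x_A <- as.numeric(stats::rbinom(1, state$x_A, p_surv))
    state$x_B <- as.numeric(stats::rbinom(1, state$x_B, p_surv))
  }
  state
}

#' Simulate one learning pair
#'
#' Repeats the stochastic increase/decrease cycle: each repetition the
#' increase process is entered with probability `alpha_inc`, and the
#' decrease process is applied per `decay_mode`, with the error recomputed
#' from the post-increase state within the same repetition (unless
#' `fixed_epsilon` is set).
#'
#' @param targets Length-2 non-negative target weights `(T_A, T_B)`.
#' @param params A [learning_params()].
#' @param n_repeats Number of repetitions (>= 1).
#' @param initial Length-2 initial values (default `c(1, 1)`).
#' @param record_stride Record the state every this many repetitions
#'   (default `n_repeats / 100`).
#' @return A data frame of class `pair_trajectory` with columns `repeat_`,
#'   `x_A`, `x_B` and `ratio` (`x_A / x_B`, `NA` when `x_B == 0`).
#' @examples
#' set.seed(1)
#' tr <- run_pair(c(1, 2), learning_params(), n_repeats = 1e4)
#' tail(tr, 3)
#' @export
run_pair <- function(targets, params = learning_params(), n_repeats,
                     initial = c(1, 1), record_stride = max(1, floor(n_repeats / 100))) {
  stopifnot(length(targets) == 2, all(targets >= 0), sum(targets) > 0,
            n_repeats >= 1, length(initial) == 2, all(initial >= 0))
  res <- cpp_run_pairs(
    xL0 = initial[1], xR0 = initial[2], tfracL = targets[1] / sum(targets),
    noDecay = FALSE,
    alphaInc = params$alpha_inc, alphaDec = params$alpha_dec,
    beta = params$beta, gamma = params$gamma,
    errMode = params$error_code, kStep = params$k,
    halfUp = params$rounding == "half_up",
    decayMode = match(params$decay_mode, c("scaled", "gated")) - 1L,
    fixedEps = params$fixed_epsilon, nRepeats = n_repeats,
    recordStride = record_stride,
    left = integer(0), right = integer(0), targetLeaf = numeric(0),
    recordStates = TRUE, alphaIncMode = 0L, alphaMin = 0, covRefreshStride = 1L)
  x_A <- res$rec_x_left[1, ]
  x_B <- res$rec_x_right[1, ]
  out <- data.frame(repeat_ = res$rec_repeat, x_A = x_A, x_B = x_B,
                    ratio = ifelse(x_B > 0, x_A / x_B, NA_real_))
  class(out) <- c("pair_trajectory", class(out))
  out
}

#' Simulate a flat list of competing factors
#'
#' All factors compete in one list: each increase selects one factor at
#' weights `(x_i + beta)`, and a single shared error — the mean over
#' factors of the squared difference between current and target fractions
#' — drives the decay of every factor.
#'
#' @param targets Non-negative target weights, one per factor (length >= 2).
#' @param params A [learning_params()].
#' @param n_repeats Number of repetitions.
#' @param initial Initial values (default all 1).
#' @param record_stride Recording stride (default `n_repeats / 100`).
#' @return A list of class `flat_run` with elements `x` (final values),
#'   `ratios` (final values normalised to sum 1), `targets`, and `records`
#'   (data frame `repeat_` plus one column per factor).
#' @export
run_flat <- function(targets, params = learning_params(), n_repeats,
                     initial = rep(1, length(targets)),
                     record_stride = max(1, floor(n_repeats / 100))) {
  n <- length(targets)
  stopifnot(n >= 2, all(targets >= 0), sum(targets) > 0,
            length(initial) == n, all(initial >= 0), n_repeats >= 1)
  res <- cpp_run_flat(
    x0 = as.numeric(initial), tfrac = targets / sum(targets),
    alphaInc = params$alpha_inc, alphaDec = params$alpha_dec,
    beta = params$beta, gamma = params$gamma,
    errMode = params$error_code, kStep = params$k,
    halfUp = params$rounding == "half_up",
    decayMode = match(params$decay_mode, c("scaled", "gated")) - 1L,
    fixedEps = params$fixed_epsilon, nRepeats = n_repeats,
    recordStride = record_stride)
  rec <- as.data.frame(t(res$rec_x))
  names(rec) <- if (!is.null(names(targets))) names(targets) else paste0("f", seq_len(n))
  rec <- cbind(repeat_ = res$rec_repeat, rec)
  x <- res$x
  structure(list(x = x, ratios = if (sum(x) > 0) x / sum(x) else rep(1 / n, n),
                 targets = targets, records = rec),
            class = "flat_run")
}
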