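#' Build a balanced hierarchical-pair architecture
#'
#' Recursively halves an ordered list of leaves (left half / right half)
#' until single leaves remain. For `n = 2^k` leaves the tree is perfect
#' with `k` layers; for other `n` the left half takes the extra leaf.
#' Every architecture over `n` leaves has exactly `n - 1` internal pairs.
#'
#' Pairs are indexed in preorder (root pair = 1, layer 1), so a parent's
#' index is always smaller than its children's — a property the
#' simulation engine relies on for single-pass path products.
#'
#' @param leaves Either a character vector of leaf (factor/gene) names in
#'   order, or a single integer `n >= 2` (names become `"f1" ... "fn"`).
#' @return An object of class `pair_tree`: a list with `n_leaves`,
#'   `n_pairs`, `layer`, `left`/`right` child encodings (positive = pair
#'   index, negative = -leaf index), branch values `x_left`/`x_right`
#'   (initialised to 1), branch targets `t_left`/`t_right` (unset), and
#'   `leaf_names`.
#' @examples
#' tr <- build_balanced_tree(8)
#' n_pairs(tr)      # 7
#' tree_layers(tr)  # 3
#' @export
build_balanced_tree <- function(leaves) {
  if (is.numeric(leaves) && length(leaves) == 1) {
    n <- as.integer(leaves)
    leaf_names <- paste0("f", seq_len(n))
  } else {
    leaf_names <- as.character(leaves)
    n <- length(leaf_names)
  }
  if (n < 2) stop("a pair architecture needs at least 2 leaves")
  np <- n - 1L
  left <- integer(np); right <- integer(np); layer <- integer(np)
  next_id <- 0L
  rec <- function(idx, lay) {
    if (length(idx) == 1L) return(-idx)
    next_id <<- next_id + 1L
    me <- next_id
    layer[me] <<- lay
    mid <- ceiling(length(idx) / 2)
    left[me] <<- rec(idx[seq_len(mid)], lay + 1L)
    right[me] <<- rec(idx[(mid + 1):length(idx)], lay + 1L)
    me
  }
  rec(seq_len(n), 1L)
  new_pair_tree(n, left, right, layer, leaf_names)
}

new_pair_tree <- function(n_leaves, left, right, layer, leaf_names) {
  np <- length(left)
  structure(list(n_leaves = n_leaves, n_pairs = np, layer = layer,
                 left = left, right = right,
                 x_left = rep(1, np), x_right = rep(1, np),
                 t_left = rep(NA_real_, np), t_right = rep(NA_real_, np),
                 leaf_names = leaf_names),
            class = "pair_tree")
}

#' @export
print.pair_tree <- function(x, ...) {
  cat(sprintf("pair_tree: %d leaves, %d pairs, %d layers\n",
              x$n_leaves, x$n_pairs, tree_layers(x)))
  if (!anyNA(x$t_left)) {
    cat(sprintf("root target %g:%g\n", x$t_left[1], x$t_right[1]))
  }
  invisible(x)
}

#' Number of pairs (internal nodes) in an architecture
#' @param tree A `pair_tree`.
#' @return Integer, always `n_leaves - 1`.
#' @export
n_pairs <- function(tree) {
  stopifnot(inherits(tree, "pair_tree"))
  tree$n_pairs
}

#' Number of layers (depth) of an architecture
#' @param tree A `pair_tree`.
#' @return Integer: maximum number of pairs on a root-to-leaf path.
#' @export
tree_layers <- function(tree) {
  stopifnot(inherits(tree, "pair_tree"))
  max(tree$layer)
}

#' Derive per-pair targets from a leaf target profile
#'
#' Each pair's local target ratio `(T_left, T_right)` is the sum of the
#' profile weights over its left/right leaf sets, so the leaf-level target
#' ratios decompose into the same path products as the branch values.
#' A pair whose both subtree sums are 0 is given a 1:1 local target and is
#' excluded from error-driven decay (its error is read as 0).
#'
#' @param tree A `pair_tree`.
#' @param profile Non-negative weights, one per leaf, in leaf order; at
#'   least one must be positive.
#' @return The tree with `t_left`/`t_right` filled in.
#' @export
set_targets <- function(tree, profile) {
  stopifnot(inherits(tree, "pair_tree"))
  profile <- as.numeric(profile)
  if (length(profile) != tree$n_leaves) stop("profile length must equal n_leaves")
  if (any(profile < 0)) stop("profile weights must be non-negative")
  if (sum(profile) <= 0) stop("profile must contain a positive weight")
  sums <- subtree_sums(tree, profile)
  tree$t_left <- sums$left
  tree$t_right <- sums$right
  tree
}

# subtree weight sums per pair branch; children before parents (ids descend)
subtree_sums <- function(tree, w) {
  np <- tree$n_pairs
  sl <- numeric(np); sr <- numeric(np)
  for (i in rev(seq_len(np))) {
    lc <- tree$left[i]; rc <- tree$right[i]
    sl[i] <- if (lc > 0) sl[lc] + sr[lc] else w[-lc]
    sr[i] <- if (rc > 0) sl[rc] + sr[rc] else w[-rc]
  }
  list(left = sl, right = sr)
}

#' Randomly permute a target profile over the leaves
#'
#' Shuffles which leaf carries which target weight (a uniform random
#' permutation); the multiset of weights is preserved. Used to test that
#' learning does not depend on how targets are assigned to positions in
#' the architecture.
#'
#' @param profile Numeric weights.
#' @return Permuted weights.
#' @export
shuffle_assignment <- function(profile) {
  profile[sample.int(length(profile))]
}

#' Initialize branch values of an architecture
#'
#' `mode = "ones"` sets every branch value to 1 (the even-distribution
#' start). `mode = "scaled_rounded"` sets each branch to
#' `round(M * branch fraction)` of a normalised initial profile, with
#' `M = n_leaves` by default — the prescription used when an initial
#' expression profile defines the starting state.
#'
#' @param tree A `pair_tree`.
#' @param profile Initial leaf weights (required for `"scaled_rounded"`).
#' @param mode `"ones"` or `"scaled_rounded"`.
#' @param M Scale for `"scaled_rounded"` (default `n_leaves`).
#' @return The tree with `x_left`/`x_right` set.
#' @export
initialize_branches <- function(tree, profile = NULL,
                                mode = c("ones", "scaled_rounded"), M = tree$n_leaves) {
  stopifnot(inherits(tree, "pair_tree"))
  mode <- match.arg(mode)
  if (mode == "ones") {
    tree$x_left <- rep(1, tree$n_pairs)
    tree$x_right <- rep(1, tree$n_pairs)
  } else {
    if (is.null(profile)) stop("scaled_rounded initialisation needs an initial profile")
    profile <- as.numeric(profile)
    stopifnot(length(profile) == tree$n_leaves, all(profile >= 0), sum(profile) > 0)
    profile <- profile / sum(profile)
    sums <- subtree_sums(tree, profile)
    tree$x_left <- round(M * sums$left)
    tree$x_right <- round(M * sums$right)
  }
  tree
}

#' Leaf expression ratios as path products
#'
#' The fraction of each leaf in the total is the product, over all pairs
#' on its root path, of the branch ratio `x_branch / (x_left + x_right)`.
#' An empty pair (both values 0) contributes 1/2 per side. The returned
#' vector is a probability vector (non-negative, sums to 1).
#'
#' @param tree A `pair_tree`.
#' @return Named numeric vector of per-leaf ratios.
#' @export
leaf_ratios <- function(tree) {
  stopifnot(inherits(tree, "pair_tree"))
  np <- tree$n_pairs
  cov <- numeric(np); cov[1] <- 1
  ratio <- numeric(tree$n_leaves)
  for (i in seq_len(np)) {
    tot <- tree$x_left[i] + tree$x_right[i]
    fl <- if (tot > 0) tree$x_left[i] / tot else 0.5
    lc <- tree$left[i]; rc <- tree$right[i]
    if (lc > 0) cov[lc] <- cov[i] * fl else ratio[-lc] <- cov[i] * fl
    if (rc > 0) cov[rc] <- cov[i] * (1 - fl) else ratio[-rc] <- cov[i] * (1 - fl)
  }
  names(ratio) <- tree$leaf_names
  ratio
}

#' Coverage of each pair in the whole
#'
#' The coverage of a pair is the product of branch ratios along the path
#' from the root down to (but not including) the pair — the fraction of
#' total activity attributable to its position. The root pair has
#' coverage 1. Current branch values are used.
#'
#' @param tree A `pair_tree`.
#' @return Numeric vector of coverages, one per pair.
#' @export
pair_coverage <- function(tree) {
  stopifnot(inherits(tree, "pair_tree"))
  np <- tree$n_pairs
  cov <- numeric(np); cov[1] <- 1
  for (i in seq_len(np)) {
    tot <- tree$x_left[i] + tree$x_right[i]
    fl <- if (tot > 0) tree$x_left[i] / tot else 0.5
    if (tree$left[i] > 0) cov[tree$left[i]] <- cov[i] * fl
    if (tree$right[i] > 0) cov[tree$right[i]] <- cov[i] * (1 - fl)
  }
  cov
}

# target left-fractions and the zero-target exclusion flag
tree_tfrac <- function(tree) {
  if (anyNA(tree$t_left)) stop("targets not set; call set_targets() first")
  tot <- tree$t_left + tree$t_right
  nod <- tot <= 0
  tf <- ifelse(nod, 0.5, tree$t_left / ifelse(nod, 1, tot))
  list(tfrac = tf, no_decay = nod)
}

#' Run the learning process on every pair of an architecture
#'
#' Every pair independently repeats the stochastic increase/decrease cycle
#' with its own local target ratio and local error, all advancing on a
#' shared repetition clock. Optionally the probability of entering the
#' increase process follows the pair's coverage:
#' `alpha_inc(pair) = alpha_min + 0.1 * coverage(pair)`, refreshed every
#' `cov_refresh_stride` repetitions.
#'
#' @param tree A `pair_tree` with targets set (see [set_targets()]).
#' @param params A [learning_params()].
#' @param n_repeats Repetitions per pair.
#' @param alpha_inc_mode `"constant"` (use `params$alpha_inc`) or
#'   `"coverage_linear"`.
#' @param alpha_min Offset of the coverage-linear mapping (default 0.001;
#'   0.01 gives the alternative 0.01–0.101 range).
#' @param cov_refresh_stride Repetitions between coverage refreshes
#'   (default 100).
#' @param record_stride Record the target correlation every this many
#'   repetitions (default `n_repeats / 100`).
#' @param record_leaf_ratios Also record the full leaf-ratio vector at
#'   every stride (default `FALSE`; adds a wide `ratio_trajectory`
#'   element with one column per leaf).
#' @return A list of class `hier_run`: the updated `tree`, final
#'   `leaf_ratios`, `records` (data frame with `repeat_` and Pearson `r`
#'   of leaf ratios vs target), `params`, and optionally
#'   `ratio_trajectory`.
#' @examples
#' set.seed(1)
#' tr <- set_targets(build_balanced_tree(8), 1:8)
#' run <- run_hierarchy(tr, learning_params(), n_repeats = 2e4)
#' round(tail(run$records$r, 1), 2)
#' @export
run_hierarchy <- function(tree, params = learning_params(), n_repeats,
                          alpha_inc_mode = c("constant", "coverage_linear"),
                          alpha_min = 0.001, cov_refresh_stride = 100,
                          record_stride = max(1, floor(n_repeats / 100)),
                          record_leaf_ratios = FALSE) {
  stopifnot(inherits(tree, "pair_tree"), n_repeats >= 1)
  alpha_inc_mode <- match.arg(alpha_inc_mode)
  tf <- tree_tfrac(tree)
  target_leaf <- leaf_target_profile(tree)
  res <- cpp_run_pairs(
    xL0 = as.numeric(tree$x_left), xR0 = as.numeric(tree$x_right),
    tfracL = tf$tfrac, noDecay = tf$no_decay,
    alphaInc = params$alpha_inc, alphaDec = params$alpha_dec,
    beta = params$beta, gamma = params$gamma,
    errMode = params$error_code, kStep = params$k,
    halfUp = params$rounding == "half_up",
    decayMode = match(params$decay_mode, c("scaled", "gated")) - 1L,
    fixedEps = params$fixed_epsilon, nRepeats = n_repeats,
    recordStride = record_stride,
    left = tree$left, right = tree$right,
    targetLeaf = target_leaf / sum(target_leaf),
    recordStates = record_leaf_ratios,
    alphaIncMode = match(alpha_inc_mode, c("constant", "coverage_linear")) - 1L,
    alphaMin = alpha_min, covRefreshStride = as.integer(cov_refresh_stride))
  tree$x_left <- res$x_left
  tree$x_right <- res$x_right
  recs <- data.frame(repeat_ = res$rec_repeat,
                     r = if (is.null(res$rec_r)) NA_real_ else res$rec_r)
  out <- list(tree = tree, leaf_ratios = leaf_ratios(tree),
              records = recs, params = params)
  if (record_leaf_ratios) {
    snap <- tree
    traj <- t(vapply(seq_along(res$rec_repeat), function(j) {
      snap$x_left <- res$rec_x_left[, j]
      snap$x_right <- res$rec_x_right[, j]
      leaf_ratios(snap)
    }, numeric(tree$n_leaves)))
    traj <- as.data.frame(traj)
    names(traj) <- tree$leaf_names
    out$ratio_trajectory <- cbind(repeat_ = res$rec_repeat, traj)
  }
  structure(out, class = "hier_run")
}

# reconstruct the leaf-level target profile from per-pair branch targets
leaf_target_profile <- function(tree) {
  np <- tree$n_pairs
  w <- numeric(tree$n_leaves)
  cov <- numeric(np); cov[1] <- 1
  # path products over target fractions give back normalised leaf weights;
  # instead accumulate absolute sums: pair branch targets are subtree sums
  for (i in seq_len(np)) {
    if (tree$left[i] < 0) w[-tree$left[i]] <- tree$t_left[i]
    if (tree$right[i] < 0) w[-tree$right[i]] <- tree$t_right[i]
  }
  w
}
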