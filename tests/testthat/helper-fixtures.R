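# shared fixtures and independent oracles

# small genes x cells matrix with named rows/cols
toy_matrix <- function(values, n_cells) {
  m <- matrix(values, ncol = n_cells, byrow = TRUE)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

# Brute-force agglomeration oracle: at every step recompute ALL pairwise
# distances among active clusters from their sum representatives and pick
# the minimum with the same (id_a, id_b) lexicographic tie-break. O(n^3)
# per run; independent of the package's incremental bookkeeping.
brute_cluster <- function(mat, distfun) {
  n <- nrow(mat)
  reps <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) reps[[i]] <- mat[i, ]
  active <- seq_len(n)
  out <- data.frame(a = integer(0), b = integer(0), distance = numeric(0),
                    new_id = integer(0))
  for (m in seq_len(n - 1)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        d <- distfun(reps[[a]], reps[[b]])
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 && (a < best$a || (a == best$a && b < best$b)))) {
          best <- list(a = a, b = b, d = d)
        }
      }
    }
    new_id <- n + m
    reps[[new_id]] <- reps[[best$a]] + reps[[best$b]]
    active <- c(setdiff(active, c(best$a, best$b)), new_id)
    out <- rbind(out, data.frame(a = best$a, b = best$b, distance = best$d,
                                 new_id = new_id))
  }
  out
}

# chi-square goodness of fit of observed counts vs expected probabilities
gof_pvalue <- function(observed, probs) {
  keep <- probs > 0
  suppressWarnings(stats::chisq.test(observed[keep], p = probs[keep] / sum(probs[keep]))$p.value)
}

# final Pearson r of one hierarchical run under a given error mode
hier_final_r <- function(n, profile, error_mode, n_repeats = 1e5, seed = NULL,
                         params = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- learning_params(error_mode = error_mode)
  tree <- set_targets(build_balanced_tree(n), profile)
  run <- run_hierarchy(tree, params, n_repeats,
                       record_stride = max(1, n_repeats %/% 4))
  run$records$r[nrow(run$records)]
}
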