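#' Initialise an mRNA pool from a target profile
#'
#' Allocates a fixed total number of transcripts over genes by
#' largest-remainder rounding of `size * normalised profile`, so the total
#' is exactly `size`. Remainder ties go to the lower gene index.
#'
#' @param profile Non-negative leaf weights (some positive).
#' @param size Total pool size (default 360000).
#' @return Integer vector of per-gene transcript counts (class
#'   `mrna_pool`), summing exactly to `size`.
#' @examples
#' init_pool(c(1, 2), size = 360000)  # 120000, 240000
#' @export
init_pool <- function(profile, size = 360000) {
  profile <- as.numeric(profile)
  stopifnot(all(profile >= 0), sum(profile) > 0, size >= 1)
  p <- profile / sum(profile)
  base <- floor(size * p)
  rem <- size * p - base
  short <- as.integer(round(size - sum(base)))
  if (short > 0) {
    idx <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  structure(as.integer(base), class = "mrna_pool", names = names(profile))
}

#' One transcription event: tree descent and pool replacement
#'
#' A pair in the top `max_entry_layer` layers is chosen with probability
#' proportional to its coverage; competitive amplification then descends
#' — at each pair the branch is selected at the `(x + beta)` ratio and
#' incremented by 1 — until the selected branch is a single leaf gene.
#' In the pool, one uniformly chosen mRNA is removed and one mRNA of the
#' selected gene is added, so the total is conserved and the new
#' transcript is always present.
#'
#' Ancestor pairs above the entry pair are not incremented.
#'
#' @param tree A `pair_tree`.
#' @param pool An [init_pool()] counts vector.
#' @param beta Bias used for every pair on the descent path.
#' @param max_entry_layer Deepest layer eligible as entry (default 7).
#' @return A list `tree`, `pool`, `gene` (selected leaf index).
#' @export
select_and_transcribe <- function(tree, pool, beta = 1, max_entry_layer = 7) {
  stopifnot(inherits(tree, "pair_tree"), length(pool) == tree$n_leaves)
  if (sum(pool) <= 0) stop("empty mRNA pool")
  cov <- pair_coverage(tree)
  cand <- which(tree$layer <= max_entry_layer)
  w <- cov[cand]
  entry <- if (sum(w) > 0) cand[sample.int(length(cand), 1, prob = w)] else cand[1]
  node <- entry
  repeat {
    pl <- (tree$x_left[node] + beta) / (tree$x_left[node] + tree$x_right[node] + 2 * beta)
    if (runif(1) < pl) {
      tree$x_left[node] <- tree$x_left[node] + 1
      child <- tree$left[node]
    } else {
      tree$x_right[node] <- tree$x_right[node] + 1
      child <- tree$right[node]
    }
    if (child > 0) node <- child else { gene <- -child; break }
  }
  drop_gene <- sample.int(tree$n_leaves, 1, prob = pool)
  pool[drop_gene] <- pool[drop_gene] - 1L
  pool[gene] <- pool[gene] + 1L
  list(tree = tree, pool = pool, gene = gene)
}

#' One decay sweep over all pairs (gated mode)
#'
#' Each pair independently enters the decrease process with probability
#' `alpha_dec`; when it does, each unit of both branch values survives
#' with probability `1 - eps`, where `eps` is the approximated local MSE.
#' Zero-target pairs are excluded.
#'
#' @param tree A `pair_tree` with targets set.
#' @param alpha_dec Gate probability (default 0.1).
#' @param error_mode Error approximation token (see [approx_error()]).
#' @param rounding Mantissa handling, `"truncate"` or `"half_up"`.
#' @return The updated tree.
#' @export
decay_pairs <- function(tree, alpha_dec = 0.1, error_mode = "stepwise",
                        rounding = c("truncate", "half_up")) {
  stopifnot(inherits(tree, "pair_tree"))
  rounding <- match.arg(rounding)
  tf <- tree_tfrac(tree)
  gated <- runif(tree$n_pairs) < alpha_dec & !tf$no_decay
  for (i in which(gated)) {
    tot <- tree$x_left[i] + tree$x_right[i]
    cur <- if (tot > 0) tree$x_left[i] / tot else 0.5
    eps <- approx_error((cur - tf$tfrac[i])^2, error_mode, rounding = rounding)
    if (eps > 0) {
      tree$x_left[i] <- stats::rbinom(1, tree$x_left[i], 1 - eps)
      tree$x_right[i] <- stats::rbinom(1, tree$x_right[i], 1 - eps)
    }
  }
  tree
}

#' Expression probability of each gene
#'
#' The per-repetition probability that the tree descent transcribes each
#' gene: the product of branch ratios over all pairs containing it.
#' Identical to [leaf_ratios()]; exported under this name for pool runs.
#'
#' @param tree A `pair_tree`.
#' @return Probability vector over leaves (sums to 1).
#' @export
expression_probability <- function(tree) {
  leaf_ratios(tree)
}

#' One phase of an mRNA-pool schedule
#'
#' @param n_repeats Repetitions in this phase.
#' @param targets Leaf target profile for this phase.
#' @param beta Bias during this phase (1 for differentiation, 1e-7 for
#'   the homeostatic regime).
#' @param error_mode Error approximation token (default `"step:4"`).
#' @return A list of class `pool_phase`.
#' @export
pool_phase <- function(n_repeats, targets, beta = 1, error_mode = "step:4") {
  stopifnot(n_repeats >= 1, all(targets >= 0), sum(targets) > 0)
  structure(list(n_repeats = n_repeats, targets = as.numeric(targets),
                 beta = beta, error_mode = error_mode),
            class = "pool_phase")
}

#' Run the mRNA-pool model over a schedule of phases
#'
#' Per repetition one [select_and_transcribe()]-style event followed by a
#' gated decay sweep is performed by the compiled engine; at phase
#' boundaries the targets, bias and error mode switch. Pearson
#' correlations of the pool ratios and of the expression probabilities
#' against the current phase target are recorded every `record_stride`
#' repeats.
#'
#' @param tree A `pair_tree` (targets are overwritten per phase).
#' @param pool An [init_pool()] counts vector.
#' @param schedule A single [pool_phase()] or a list of them.
#' @param alpha_dec Per-pair gate probability of the decrease process
#'   (default 0.1: decay every 10 repetitions on average).
#' @param max_entry_layer Deepest entry layer for the descent (default 7;
#'   all layers if the tree is shallower).
#' @param record_stride Recording stride in repeats (default 250).
#' @param decay_event `"per_pair"` (each pair gated independently) or
#'   `"global"` (one gate applies to all pairs at once).
#' @param rounding Mantissa handling for the approximated error.
#' @param track_genes Optional leaf indices or names whose pool counts
#'   are recorded at each stride.
#' @return A list of class `pool_run`: updated `tree`, final `pool`
#'   counts, `records` (data frame `repeat_`, `phase`, `r_pool`,
#'   `r_prob`, and one `n_<gene>` column per tracked gene).
#' @export
run_pool <- function(tree, pool, schedule, alpha_dec = 0.1, max_entry_layer = 7,
                     record_stride = 250,
                     decay_event = c("per_pair", "global"),
                     rounding = c("truncate", "half_up"),
                     track_genes = NULL) {
  stopifnot(inherits(tree, "pair_tree"), length(pool) == tree$n_leaves)
  decay_event <- match.arg(decay_event)
  rounding <- match.arg(rounding)
  if (inherits(schedule, "pool_phase")) schedule <- list(schedule)
  stopifnot(length(schedule) >= 1)
  if (is.character(track_genes)) track_genes <- match(track_genes, tree$leaf_names)
  track_genes <- as.integer(track_genes)

  counts <- as.numeric(pool)
  recs <- vector("list", length(schedule))
  done <- 0
  for (ph in seq_along(schedule)) {
    phase <- schedule[[ph]]
    stopifnot(inherits(phase, "pool_phase"),
              length(phase$targets) == tree$n_leaves)
    tree <- set_targets(tree, phase$targets)
    tf <- tree_tfrac(tree)
    em <- parse_error_mode(phase$error_mode)
    res <- cpp_run_pool(
      left = tree$left, right = tree$right, layer = tree$layer,
      xL0 = as.numeric(tree$x_left), xR0 = as.numeric(tree$x_right),
      tfracL = tf$tfrac, noDecay = tf$no_decay, counts0 = counts,
      beta = phase$beta, alphaDec = alpha_dec,
      errMode = em$code, kStep = em$k, halfUp = rounding == "half_up",
      maxEntryLayer = as.integer(max_entry_layer),
      nRepeats = phase$n_repeats, recordStride = record_stride,
      targetLeaf = phase$targets / sum(phase$targets),
      decayEvent = match(decay_event, c("per_pair", "global")) - 1L,
      trackGenes = track_genes)
    tree$x_left <- res$x_left
    tree$x_right <- res$x_right
    counts <- res$counts
    rec <- data.frame(repeat_ = done + res$rec_repeat, phase = ph,
                      r_pool = res$rec_r_pool, r_prob = res$rec_r_prob)
    if (length(track_genes) > 0) {
      tg <- as.data.frame(t(res$rec_track))
      names(tg) <- paste0("n_", tree$leaf_names[track_genes])
      rec <- cbind(rec, tg)
    }
    recs[[ph]] <- rec
    done <- done + phase$n_repeats
  }
  pool_out <- structure(as.integer(round(counts)), class = "mrna_pool",
                        names = tree$leaf_names)
  structure(list(tree = tree, pool = pool_out, records = do.call(rbind, recs)),
            class = "pool_run")
}
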