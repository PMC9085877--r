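#' Newick string of a pair architecture
#'
#' Branch-free topology with named leaves, e.g. `((a,b),(c,d));`.
#'
#' @param tree A `pair_tree`.
#' @return A single Newick string.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "pair_tree"))
  lab <- gsub("[(),:;\\s]", "_", tree$leaf_names)
  # children have larger indices, so building bottom-up in reverse id
  # order guarantees both child strings exist when a pair is assembled
  part <- character(tree$n_pairs)
  str_of <- function(child) if (child > 0) part[child] else lab[-child]
  for (i in rev(seq_len(tree$n_pairs))) {
    part[i] <- paste0("(", str_of(tree$left[i]), ",", str_of(tree$right[i]), ")")
  }
  paste0(part[1], ";")
}

#' Serialise a pair architecture to a data frame
#'
#' One row per pair: identifier, layer, child encodings (positive = pair
#' id, negative = -leaf id), branch values and branch targets.
#'
#' @param tree A `pair_tree`.
#' @return A data frame with columns `pair_id`, `layer`, `left`,
#'   `right`, `x_left`, `x_right`, `t_left`, `t_right`.
#' @export
tree_table <- function(tree) {
  stopifnot(inherits(tree, "pair_tree"))
  data.frame(pair_id = seq_len(tree$n_pairs), layer = tree$layer,
             left = tree$left, right = tree$right,
             x_left = tree$x_left, x_right = tree$x_right,
             t_left = tree$t_left, t_right = tree$t_right)
}

#' Write an architecture as Newick plus CSV
#'
#' @param tree A `pair_tree`.
#' @param newick_path Output path for the Newick topology.
#' @param csv_path Output path for the pair table ([tree_table()]).
#' @return Invisibly, the tree.
#' @export
write_architecture <- function(tree, newick_path, csv_path) {
  writeLines(tree_newick(tree), newick_path)
  write.csv(tree_table(tree), csv_path, row.names = FALSE)
  invisible(tree)
}

#' Rebuild a pair architecture from its CSV table
#'
#' Inverse of [tree_table()]/[write_architecture()].
#'
#' @param csv_path Path to a pair-table CSV.
#' @param leaf_names Optional leaf names (defaults to `f<i>`).
#' @return A `pair_tree`.
#' @export
read_architecture <- function(csv_path, leaf_names = NULL) {
  df <- read.csv(csv_path)
  need <- c("pair_id", "layer", "left", "right", "x_left", "x_right", "t_left", "t_right")
  if (!all(need %in% names(df))) stop("not a pair-table CSV")
  n <- nrow(df) + 1L
  if (is.null(leaf_names)) leaf_names <- paste0("f", seq_len(n))
  tree <- new_pair_tree(n, as.integer(df$left), as.integer(df$right),
                        as.integer(df$layer), leaf_names)
  tree$x_left <- df$x_left
  tree$x_right <- df$x_right
  tree$t_left <- df$t_left
  tree$t_right <- df$t_right
  tree
}
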