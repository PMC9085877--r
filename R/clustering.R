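#' Triangle-area distance between two expression vectors
#'
#' The area spanned by two vectors from the origin:
#' `0.5 * sqrt(|U|^2 |V|^2 - (U.V)^2)`. It is 0 exactly when the vectors
#' are parallel (constant expression ratio across cells) or one is zero,
#' and it scales linearly with either vector's magnitude, so highly
#' expressed genes carry large distances and join high layers late.
#'
#' @param U,V Non-negative numeric vectors of equal length (expression
#'   over cells).
#' @return Non-negative scalar.
#' @examples
#' area_distance(c(1, 0), c(0, 1))  # 0.5
#' area_distance(c(2, 4), c(1, 2))  # 0: parallel
#' @export
area_distance <- function(U, V) {
  stopifnot(length(U) == length(V))
  g <- sum(U * U) * sum(V * V) - sum(U * V)^2
  0.5 * sqrt(max(g, 0))
}

#' Coefficient-of-variation distance between two expression vectors
#'
#' The total expression of the pair, `U + V`, is formed per cell, and the
#' coefficient of variation (population standard deviation / mean) of
#' that sum across cells is the distance. Family genes with functional
#' substitutability — complementary, constant-sum expression — get
#' distance 0.
#'
#' @inheritParams area_distance
#' @return Non-negative scalar.
#' @examples
#' cv_distance(c(1, 0), c(0, 1))  # 0: constant sum
#' cv_distance(c(2, 0), c(0, 1))  # sd(c(2,1))/mean(c(2,1)) = 1/3
#' @export
cv_distance <- function(U, V) {
  stopifnot(length(U) == length(V))
  s <- U + V
  m <- mean(s)
  if (m <= 0) stop("cv_distance undefined: U + V is all zeros")
  sqrt(mean((s - m)^2)) / m
}

#' Product of the area and cv distances
#'
#' @inheritParams area_distance
#' @return `area_distance(U, V) * cv_distance(U, V)`.
#' @export
cvarea_distance <- function(U, V) {
  area_distance(U, V) * cv_distance(U, V)
}

#' Representative expression vector of a gene cluster
#'
#' The elementwise sum of the member genes' rows: pairing in the
#' learning-pair model splits total expression into two subgroups, so the
#' total is the natural cluster summary.
#'
#' @param genes Row indices or names of the cluster members.
#' @param matrix Genes x cells non-negative expression matrix.
#' @return Numeric vector over cells.
#' @export
representative <- function(genes, matrix) {
  m <- matrix[genes, , drop = FALSE]
  colSums(m)
}

#' Agglomerative clustering of genes into a pair architecture
#'
#' Repeats two calculations until one cluster holds all genes: (1) merge
#' the two genes/clusters at the smallest distance, (2) compute distances
#' from the new cluster to all others. For the three sum-representative
#' methods (`AreaSum`, `CvSum`, `Cvarea`) the new cluster's distances are
#' recomputed from its summed expression vector. The three baselines
#' delegate to [stats::hclust()] with their standard linkage recurrences:
#' `Ward` (Euclidean distance, Ward's criterion), `WCO` (cosine distance,
#' WPGMA linkage) and `Single` (Euclidean distance, single linkage).
#'
#' Ties among equal minimal distances are broken by the lexicographically
#' smallest (cluster id A, cluster id B), so dendrograms are
#' deterministic.
#'
#' @param matrix Genes x cells non-negative numeric matrix with row names.
#' @param method One of `"AreaSum"`, `"CvSum"`, `"Cvarea"`, `"Ward"`,
#'   `"WCO"`, `"Single"`.
#' @param cv `"population"` (n-denominator, default) or `"sample"`
#'   standard deviation in the cv-based distances.
#' @return An object of class `merge_history`: a data frame with one row
#'   per merge (`a`, `b`, `distance`, `new_id`; singletons are ids
#'   `1..n`, merges `n+1..2n-1`), with attributes `n_genes`,
#'   `gene_names` and `method`. Convert with [history_to_tree()].
#' @export
cluster_expression <- function(matrix,
                               method = c("AreaSum", "CvSum", "Cvarea",
                                          "Ward", "WCO", "Single"),
                               cv = c("population", "sample")) {
  method <- match.arg(method)
  cv <- match.arg(cv)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) stop("need at least 2 genes and 2 cells")
  if (any(matrix < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(matrix))) rownames(matrix) <- paste0("g", seq_len(nrow(matrix)))
  n <- nrow(matrix)

  if (method %in% c("Ward", "WCO", "Single")) {
    hc <- switch(method,
      Ward = stats::hclust(stats::dist(matrix), method = "ward.D2"),
      Single = stats::hclust(stats::dist(matrix), method = "single"),
      WCO = stats::hclust(stats::as.dist(cosine_distance_matrix(matrix)),
                          method = "mcquitty"))
    return(hclust_to_history(hc, rownames(matrix), method))
  }

  distfun <- switch(method,
    AreaSum = area_distance,
    CvSum = function(U, V) cv_dist_impl(U, V, cv),
    Cvarea = function(U, V) area_distance(U, V) * cv_dist_impl(U, V, cv))

  # greedy agglomeration on sum representatives
  total <- 2L * n - 1L
  reps <- matrix(0, nrow = total, ncol = ncol(matrix))
  reps[seq_len(n), ] <- matrix
  active <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  D <- base::matrix(Inf, total, total)
  act <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) D[i, j] <- distfun(reps[i, ], reps[j, ])

  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       distance = numeric(n - 1L), new_id = integer(n - 1L))
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # lexicographic tie-break on (id_a, id_b); upper triangle so row < col
    best <- best[order(act[best[, 1]], act[best[, 2]]), , drop = FALSE]
    a <- act[best[1, 1]]; b <- act[best[1, 2]]
    new_id <- n + m
    merges[m, ] <- list(a, b, D[a, b], new_id)
    reps[new_id, ] <- reps[a, ] + reps[b, ]
    active[c(a, b)] <- FALSE
    active[new_id] <- TRUE
    for (o in which(active)) {
      if (o == new_id) next
      d <- distfun(reps[o, ], reps[new_id, ])
      D[min(o, new_id), max(o, new_id)] <- d
    }
  }
  structure(merges, class = c("merge_history", "data.frame"),
            n_genes = n, gene_names = rownames(matrix), method = method)
}

cv_dist_impl <- function(U, V, cv) {
  d <- cv_distance(U, V)
  if (cv == "sample") {
    nn <- length(U)
    d <- d * sqrt(nn / (nn - 1))
  }
  d
}

cosine_distance_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cosine distance undefined for all-zero gene rows")
  sim <- (m %*% t(m)) / outer(nrm, nrm)
  1 - sim
}

hclust_to_history <- function(hc, gene_names, method) {
  n <- length(gene_names)
  id_of <- function(v) ifelse(v < 0, -v, n + v)
  a <- id_of(hc$merge[, 1]); b <- id_of(hc$merge[, 2])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  structure(data.frame(a = a, b = b, distance = hc$height,
                       new_id = n + seq_len(n - 1L)),
            class = c("merge_history", "data.frame"),
            n_genes = n, gene_names = gene_names, method = method)
}

#' @export
print.merge_history <- function(x, ...) {
  cat(sprintf("merge_history (%s): %d genes, %d pairs, %d layers\n",
              attr(x, "method"), attr(x, "n_genes"), nrow(x), cluster_layers(x)))
  invisible(x)
}

#' Convert a merge history to a pair architecture
#'
#' The final merged cluster becomes the root pair; each merge's two
#' constituents become its branches. Pair indices are assigned in
#' preorder.
#'
#' @param history A `merge_history` from [cluster_expression()].
#' @return A `pair_tree` over the clustered genes.
#' @export
history_to_tree <- function(history) {
  stopifnot(inherits(history, "merge_history"))
  n <- attr(history, "n_genes")
  gene_names <- attr(history, "gene_names")
  child_a <- integer(n - 1L); child_b <- integer(n - 1L)
  child_a[history$new_id - n] <- history$a
  child_b[history$new_id - n] <- history$b
  np <- n - 1L
  left <- integer(np); right <- integer(np); layer <- integer(np)
  # explicit-stack preorder traversal: merge chains can be O(n) deep
  stack <- matrix(0L, nrow = 2L * np + 1L, ncol = 4L)  # cid, parent, side, layer
  top <- 1L
  stack[1L, ] <- c(2L * n - 1L, 0L, 0L, 1L)
  next_id <- 0L
  while (top > 0L) {
    cid <- stack[top, 1L]; parent <- stack[top, 2L]
    side <- stack[top, 3L]; lay <- stack[top, 4L]
    top <- top - 1L
    if (cid <= n) {
      if (side == 1L) left[parent] <- -cid else right[parent] <- -cid
      next
    }
    next_id <- next_id + 1L
    me <- next_id
    layer[me] <- lay
    if (parent > 0L) {
      if (side == 1L) left[parent] <- me else right[parent] <- me
    }
    top <- top + 1L
    stack[top, ] <- c(child_b[cid - n], me, 2L, lay + 1L)
    top <- top + 1L
    stack[top, ] <- c(child_a[cid - n], me, 1L, lay + 1L)
  }
  new_pair_tree(n, left, right, layer, gene_names)
}

#' Number of layers of the architecture implied by a merge history
#'
#' @param history A `merge_history`.
#' @return Integer depth: the maximum number of pairs on any
#'   root-to-leaf path (between `ceiling(log2(n))` and `n - 1`).
#' @export
cluster_layers <- function(history) {
  stopifnot(inherits(history, "merge_history"))
  n <- attr(history, "n_genes")
  depth <- integer(2L * n - 1L)  # depth of each cluster's subtree, leaves 0
  ha <- history$a; hb <- history$b; hn <- history$new_id
  for (m in seq_along(hn)) {
    depth[hn[m]] <- 1L + max(depth[ha[m]], depth[hb[m]])
  }
  depth[2L * n - 1L]
}
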