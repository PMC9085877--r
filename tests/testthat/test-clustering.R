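test_that("area distance is the triangle area, zero iff parallel", {
  expect_equal(area_distance(c(1, 0), c(0, 1)), 0.5)
  expect_equal(area_distance(c(2, 4), c(1, 2)), 0)
  expect_equal(area_distance(3 * c(1, 0), c(0, 1)), 3 * 0.5)  # homogeneity
  set.seed(1)
  for (i in 1:20) {
    U <- runif(5); V <- runif(5)
    expect_equal(area_distance(U, V), area_distance(V, U))
    expect_gte(area_distance(U, V), 0)
    # parallel vectors: zero up to Gram-determinant cancellation error
    expect_lt(area_distance(U, 2.5 * U), 1e-6)
  }
})

test_that("cv distance vanishes for constant-sum pairs", {
  expect_equal(cv_distance(c(1, 0), c(0, 1)), 0)
  expect_equal(cv_distance(c(2, 0), c(0, 1)), (0.5) / 1.5)
  expect_equal(cvarea_distance(c(2, 0), c(0, 1)),
               area_distance(c(2, 0), c(0, 1)) * (1 / 3))
  expect_equal(cvarea_distance(c(2, 4), c(1, 2)), 0)  # parallel
  expect_error(cv_distance(c(0, 0), c(0, 0)), "all zeros")
})

test_that("cluster representatives are additive sums up to the column totals", {
  m <- toy_matrix(c(1, 2, 3,
                    4, 5, 6,
                    7, 8, 9), 3)
  expect_equal(representative("g1", m), m["g1", ])
  expect_equal(representative(c("g1", "g3"), m),
               representative("g1", m) + representative("g3", m))
  expect_equal(representative(rownames(m), m), colSums(m))
})

test_that("agglomeration yields n - 1 merges convertible to a pair tree", {
  set.seed(2)
  m <- toy_matrix(runif(8 * 4), 4)
  for (method in c("AreaSum", "CvSum", "Cvarea", "Ward", "WCO", "Single")) {
    h <- cluster_expression(m, method)
    expect_equal(nrow(h), 7, info = method)
    tr <- history_to_tree(h)
    expect_equal(n_pairs(tr), 7, info = method)
    expect_setequal(tr$leaf_names, rownames(m))
    expect_equal(tree_layers(tr), cluster_layers(h), info = method)
    expect_gte(cluster_layers(h), 3)
    expect_lte(cluster_layers(h), 7)
  }
  # two genes: one merge regardless of method
  m2 <- toy_matrix(c(1, 2, 5, 1), 2)
  for (method in c("AreaSum", "CvSum", "Ward"))
    expect_equal(nrow(cluster_expression(m2, method)), 1)
})

test_that("AreaSum merges proportional (constant-ratio) genes before others", {
  # three groups of pairwise-proportional rows with distinct directions
  set.seed(3)
  dirs <- rbind(c(1, 0, 0.2, 0.1), c(0.1, 1, 0, 0.3), c(0.2, 0.1, 1, 0))
  m <- do.call(rbind, lapply(1:3, function(g) {
    do.call(rbind, lapply(c(1, 2.5, 7), function(s) s * dirs[g, ]))
  }))
  rownames(m) <- paste0("g", 1:9)
  group <- rep(1:3, each = 3)
  h <- cluster_expression(m, "AreaSum")
  # first merges are all within-group (distance 0); find the first
  # between-group merge and check every within-group pair merged earlier
  member_groups <- as.list(group)
  for (i in seq_len(nrow(h))) {
    ga <- member_groups[[h$a[i]]]; gb <- member_groups[[h$b[i]]]
    cross <- length(unique(c(ga, gb))) > 1
    if (i <= 6) expect_false(cross, info = paste("merge", i))
    member_groups[[h$new_id[i]]] <- c(ga, gb)
  }
})

test_that("CvSum pairs complementary constant-sum genes first", {
  # family pairs with complementary expression across 4 cells
  m <- toy_matrix(c(9, 1, 5, 3,
                    1, 9, 5, 7,   # g1+g2 = (10,10,10,10)
                    8, 2, 1, 6,
                    0, 6, 7, 2,   # g3+g4 = (8,8,8,8)
                    5, 9, 2, 7), 4)
  h <- cluster_expression(m, "CvSum")
  first_two <- h[1:2, c("a", "b")]
  pairs <- apply(first_two, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(pairs, c("1-2", "3-4"))
})

test_that("incremental greedy merging equals the full re-scan oracle exactly", {
  set.seed(4)
  dists <- list(AreaSum = area_distance, CvSum = cv_distance, Cvarea = cvarea_distance)
  for (rep_i in 1:3) {
    n <- sample(6:12, 1)
    m <- toy_matrix(round(runif(n * 5, 0, 10), 2) + 0.01, 5)
    for (method in names(dists)) {
      h <- cluster_expression(m, method)
      oracle <- brute_cluster(m, dists[[method]])
      expect_equal(h$a, oracle$a, info = method)
      expect_equal(h$b, oracle$b, info = method)
      expect_equal(h$distance, oracle$distance, tolerance = 1e-12, info = method)
    }
  }
})

test_that("baseline linkages behave as their standard algorithms", {
  set.seed(5)
  # single linkage on collinear points chains into a caterpillar
  m <- matrix(c(1, 2, 4, 8, 16, 32), ncol = 1)
  m <- cbind(m, 0)
  rownames(m) <- paste0("g", 1:6)
  h <- cluster_expression(m, "Single")
  expect_equal(cluster_layers(h), 5)  # n - 1 layers: fully chained
  # WCO: cosine distance ignores magnitude; proportional genes merge first
  m2 <- toy_matrix(c(1, 2, 10, 20, 5, 1, 1, 5), 2)
  h2 <- cluster_expression(m2, "WCO")
  expect_equal(sort(c(h2$a[1], h2$b[1])), c(1, 2))
})
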