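test_that("balanced trees have n - 1 pairs and log-depth layers", {
  t8 <- build_balanced_tree(8)
  expect_equal(n_pairs(t8), 7)
  expect_equal(tree_layers(t8), 3)
  t2 <- build_balanced_tree(2)
  expect_equal(n_pairs(t2), 1)
  expect_equal(tree_layers(t2), 1)
  t4096 <- build_balanced_tree(4096)
  expect_equal(n_pairs(t4096), 4095)
  expect_equal(tree_layers(t4096), 12)
  for (n in c(3, 5, 6, 7, 11, 100)) {
    tr <- build_balanced_tree(n)
    expect_equal(n_pairs(tr), n - 1)
    expect_gte(tree_layers(tr), ceiling(log2(n)))
    expect_lte(tree_layers(tr), n - 1)
    # every leaf appears exactly once as a child
    leaves <- -c(tr$left, tr$right)
    expect_setequal(leaves[leaves > 0], seq_len(n))
  }
  expect_error(build_balanced_tree(1), "at least 2")
})

test_that("pair targets are subtree sums of the leaf profile", {
  tr <- set_targets(build_balanced_tree(4), c(1, 2, 3, 4))
  expect_equal(c(tr$t_left[1], tr$t_right[1]), c(3, 7))   # root 3:7
  # children of the root in preorder: pair 2 = leaves 1,2; pair 3 = leaves 3,4
  expect_equal(c(tr$t_left[2], tr$t_right[2]), c(1, 2))
  expect_equal(c(tr$t_left[3], tr$t_right[3]), c(3, 4))
  # uniform profile: every pair balanced
  tru <- set_targets(build_balanced_tree(4), rep(1, 4))
  expect_true(all(tru$t_left == tru$t_right))
  # permuting the profile re-derives targets consistently
  set.seed(1)
  prof <- shuffle_assignment(c(1, 2, 3, 4))
  trs <- set_targets(build_balanced_tree(4), prof)
  expect_equal(trs$t_left[1] + trs$t_right[1], 10)
  expect_setequal(c(trs$t_left[2:3], trs$t_right[2:3]), 1:4)
})

test_that("leaf ratios are path products forming a probability vector", {
  tr <- build_balanced_tree(4)  # all x = 1: every pair 1:1
  expect_equal(unname(leaf_ratios(tr)), rep(0.25, 4))
  tr$x_left[1] <- 1; tr$x_right[1] <- 3
  expect_equal(unname(leaf_ratios(tr)), c(0.125, 0.125, 0.375, 0.375))
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    trr <- build_balanced_tree(n)
    trr$x_left <- sample(0:50, n - 1, replace = TRUE)
    trr$x_right <- sample(0:50, n - 1, replace = TRUE)
    lr <- leaf_ratios(trr)
    expect_true(all(lr >= 0))
    expect_lt(abs(sum(lr) - 1), 1e-12 * n)
  }
})

test_that("coverage is the root-path product and layers sum to at most one", {
  tr <- build_balanced_tree(8)  # uniform state: all pairs 1:1
  cov <- pair_coverage(tr)
  expect_equal(cov[1], 1)
  expect_equal(cov[tr$layer == 2], rep(0.5, 2))
  for (lay in 1:3) expect_lte(sum(cov[tr$layer == lay]), 1 + 1e-12)
})

test_that("branch initialisation supports even and profile-scaled starts", {
  tr <- build_balanced_tree(4)
  tr1 <- initialize_branches(tr, mode = "ones")
  expect_true(all(tr1$x_left == 1) && all(tr1$x_right == 1))
  tr2 <- initialize_branches(tr, rep(1, 4), "scaled_rounded", M = 4)
  expect_equal(tr2$x_left[1], 2)  # round(4 * 0.5)
  expect_equal(tr2$x_right[1], 2)
  # general prescription: branch value = round(M * branch fraction)
  tr3 <- initialize_branches(tr, c(1, 2, 3, 4), "scaled_rounded", M = 1000)
  expect_equal(tr3$x_left[1], round(1000 * 0.3))
  expect_equal(tr3$x_right[1], round(1000 * 0.7))
})

test_that("shuffling preserves the multiset of target weights", {
  set.seed(3)
  w <- c(5, 1, 1, 9, 2)
  s1 <- shuffle_assignment(w)
  expect_setequal(s1, w)
  expect_equal(sort(shuffle_assignment(s1)), sort(w))
})

test_that("a two-leaf hierarchy run reproduces the single-pair engine bit for bit", {
  tr <- set_targets(build_balanced_tree(2), c(1, 2))
  set.seed(9)
  hr <- run_hierarchy(tr, learning_params(), n_repeats = 1e4, record_stride = 1e3)
  set.seed(9)
  pr <- run_pair(c(1, 2), learning_params(), n_repeats = 1e4, record_stride = 1e3)
  expect_identical(hr$tree$x_left[1], pr$x_A[nrow(pr)])
  expect_identical(hr$tree$x_right[1], pr$x_B[nrow(pr)])
})

test_that("learning progresses: correlation rises from 1e3 to 1e5 repeats", {
  rs <- t(sapply(1:5, function(s) {
    set.seed(s)
    tr <- set_targets(build_balanced_tree(64), 1:64)
    run <- run_hierarchy(tr, learning_params(), n_repeats = 1e5, record_stride = 1e3)
    c(early = run$records$r[1], late = run$records$r[nrow(run$records)])
  }))
  expect_gt(median(rs[, "late"]), median(rs[, "early"]))
  expect_gt(median(rs[, "late"]), 0.95)
})

test_that("shuffled target assignment learns as well as the ordered one", {
  ordered_r <- sapply(1:8, function(s) hier_final_r(64, 1:64, "exact", 5e4, seed = s))
  shuffled_r <- sapply(1:8, function(s) {
    set.seed(1000 + s)
    hier_final_r(64, shuffle_assignment(1:64), "exact", 5e4)
  })
  qo <- quantile(ordered_r, c(0.25, 0.75))
  qs <- quantile(shuffled_r, c(0.25, 0.75))
  expect_true(qo[1] <= qs[2] && qs[1] <= qo[2])  # overlapping interquartile ranges
})

test_that("coverage-linear alpha_inc runs and still learns", {
  set.seed(10)
  tr <- set_targets(build_balanced_tree(16), 1:16)
  run <- run_hierarchy(tr, learning_params(error_mode = "stepwise"), n_repeats = 5e4,
                       alpha_inc_mode = "coverage_linear", alpha_min = 0.001)
  expect_gt(run$records$r[nrow(run$records)], 0.7)
})

test_that("recorded leaf-ratio trajectories are probability vectors ending at the final state", {
  set.seed(11)
  tr <- set_targets(build_balanced_tree(8), 1:8)
  run <- run_hierarchy(tr, learning_params(), n_repeats = 5e3,
                       record_stride = 500, record_leaf_ratios = TRUE)
  traj <- run$ratio_trajectory
  expect_equal(nrow(traj), 10)
  sums <- rowSums(traj[, -1])
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_equal(unlist(traj[nrow(traj), -1], use.names = FALSE),
               unname(run$leaf_ratios))
})

test_that("architecture serialisation round-trips through Newick and CSV", {
  tr <- set_targets(build_balanced_tree(paste0("gene", 1:6)), c(3, 1, 4, 1, 5, 9))
  nwk <- tree_newick(tr)
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_equal(length(phy$tip.label), 6)
  expect_setequal(phy$tip.label, tr$leaf_names)
  tmp_nwk <- tempfile(fileext = ".nwk"); tmp_csv <- tempfile(fileext = ".csv")
  write_architecture(tr, tmp_nwk, tmp_csv)
  back <- read_architecture(tmp_csv, leaf_names = tr$leaf_names)
  expect_equal(back$left, tr$left)
  expect_equal(back$right, tr$right)
  expect_equal(back$t_left, tr$t_left)
  expect_equal(leaf_ratios(back), leaf_ratios(tr))
})
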