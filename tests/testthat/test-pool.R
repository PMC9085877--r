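test_that("pool initialisation uses largest-remainder rounding to the exact size", {
  expect_equal(as.integer(init_pool(rep(1, 4), size = 8)), rep(2L, 4))
  expect_equal(as.integer(init_pool(c(1, 2), size = 360000)), c(120000L, 240000L))
  set.seed(1)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    p <- runif(n)
    size <- sample(10:5000, 1)
    pool <- init_pool(p, size)
    expect_equal(sum(pool), size)
    expect_true(all(pool >= 0))
  }
})

test_that("transcription descends to one gene and conserves the pool", {
  tr <- set_targets(build_balanced_tree(2), c(1, 1))
  pool <- init_pool(c(10, 0), size = 10)
  set.seed(2)
  out <- select_and_transcribe(tr, pool)
  expect_equal(sum(out$pool), 10)
  expect_gte(out$pool[out$gene], 1)  # the new transcript is always present
  # exactly one branch increment per pair on the path (depth-1 tree: one)
  expect_equal(sum(out$tree$x_left + out$tree$x_right) -
                 sum(tr$x_left + tr$x_right), 1)
})

test_that("a uniform tree transcribes each gene equally often", {
  tr <- set_targets(build_balanced_tree(4), rep(1, 4))
  pool <- init_pool(rep(1, 4), size = 400)
  set.seed(3)
  genes <- replicate(4000, select_and_transcribe(tr, pool)$gene)
  expect_gt(gof_pvalue(tabulate(genes, 4), rep(0.25, 4)), 1e-3)
})

test_that("descent increments exactly the path from entry pair to leaf", {
  tr <- set_targets(build_balanced_tree(8), 1:8)
  set.seed(4)
  for (i in 1:20) {
    before <- sum(tr$x_left + tr$x_right)
    out <- select_and_transcribe(tr, init_pool(rep(1, 8), 80))
    added <- sum(out$tree$x_left + out$tree$x_right) - before
    expect_gte(added, 1)             # at least the entry pair
    expect_lte(added, tree_layers(tr))
  }
})

test_that("gated pair decay has the analytic mean loss", {
  tr <- set_targets(build_balanced_tree(2), c(1, 2))
  tr$x_left[1] <- 1000; tr$x_right[1] <- 1000
  # current fraction 1/2 vs target 1/3: MSE = 1/36 -> stepwise eps = 0.01
  # expected loss per call per branch: alpha_dec * x * eps = 0.1*1000*0.01 = 1
  set.seed(5)
  losses <- replicate(4000, {
    d <- decay_pairs(tr, alpha_dec = 0.1, error_mode = "stepwise")
    1000 - d$x_left[1]
  })
  expect_lt(abs(mean(losses) - 1), 0.25)
  expect_identical(decay_pairs(tr, alpha_dec = 0), tr)
})

test_that("expression probability equals leaf ratios and sums to one", {
  set.seed(6)
  tr <- build_balanced_tree(16)
  tr$x_left <- sample(0:30, 15, replace = TRUE)
  tr$x_right <- sample(0:30, 15, replace = TRUE)
  expect_identical(expression_probability(tr), leaf_ratios(tr))
  expect_equal(sum(expression_probability(tr)), 1)
})

test_that("pool runs conserve the pool and record probability vectors", {
  tr <- build_balanced_tree(8)
  tr <- initialize_branches(tr, rep(1, 8), "scaled_rounded", M = 8)
  pool <- init_pool(rep(1, 8), size = 8000)
  set.seed(7)
  run <- run_pool(tr, pool, pool_phase(2e4, 1:8, beta = 1, error_mode = "step:4"),
                  record_stride = 500, track_genes = c("f1", "f8"))
  expect_equal(sum(run$pool), 8000)
  expect_true(all(run$pool >= 0))
  expect_true(all(diff(run$records$repeat_) > 0))
  expect_true(all(abs(run$records$r_pool) <= 1, na.rm = TRUE))
  expect_true(sum(leaf_ratios(run$tree)) - 1 < 1e-10)
  expect_true(all(c("n_f1", "n_f8") %in% names(run$records)))
  # tracked counts are within the pool
  expect_true(all(run$records$n_f1 >= 0 & run$records$n_f1 <= 8000))
})

test_that("multi-phase schedules switch targets at phase boundaries", {
  tr <- build_balanced_tree(8)
  tr <- initialize_branches(tr, 8:1, "scaled_rounded", M = 64)
  pool <- init_pool(8:1, size = 4000)
  set.seed(8)
  run <- run_pool(tr, pool,
                  list(pool_phase(1e4, 8:1, error_mode = "step:4"),
                       pool_phase(1e5, 1:8, error_mode = "step:4")),
                  record_stride = 500)
  rec <- run$records
  expect_equal(unique(rec$phase), c(1, 2))
  # after relearning the pattern has flipped to the second target
  r_new <- ratio_correlation(as.numeric(run$pool), 1:8)
  r_old <- ratio_correlation(as.numeric(run$pool), 8:1)
  expect_gt(r_new, 0.3)
  expect_gt(r_new, r_old)
  expect_equal(sum(run$pool), 4000)
})

test_that("sibling leaves fluctuate together more than root-separated leaves", {
  # leaves 1,2 are siblings in the deepest layer; leaves 1,8 split at the root
  rs <- t(sapply(1:10, function(s) {
    set.seed(s)
    tr <- build_balanced_tree(8)
    tr <- initialize_branches(tr, rep(1, 8), "scaled_rounded", M = 800)
    run <- run_pool(tr, init_pool(rep(1, 8), 8000),
                    pool_phase(3e4, rep(1, 8), error_mode = "step:3"),
                    record_stride = 250, track_genes = c("f1", "f2", "f8"))
    rec <- run$records
    c(sib = cor(rec$n_f1, rec$n_f2), far = cor(rec$n_f1, rec$n_f8))
  }))
  expect_gt(mean(rs[, "sib"], na.rm = TRUE), mean(rs[, "far"], na.rm = TRUE))
})

test_that("single-step R operations agree with the compiled engine statistically", {
  # mean leaf selection frequencies over many single steps match a short
  # engine run on the same uniform state
  tr <- set_targets(build_balanced_tree(4), rep(1, 4))
  set.seed(9)
  r_genes <- replicate(3000, select_and_transcribe(tr, init_pool(rep(1, 4), 40))$gene)
  pool0 <- init_pool(rep(1, 4), size = 4e5)
  run <- run_pool(build_balanced_tree(4), pool0,
                  pool_phase(3000, rep(1, 4)), alpha_dec = 0, record_stride = 3000)
  engine_added <- as.integer(run$pool) - as.integer(pool0)
  # both should be near-uniform over the 4 genes
  expect_gt(gof_pvalue(tabulate(r_genes, 4), rep(0.25, 4)), 1e-3)
  removed <- sum(pmax(-engine_added, 0))
  expect_equal(sum(engine_added), 0)  # replacement conserves the total
})
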