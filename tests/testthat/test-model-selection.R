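test_that("node scan finds the generating shift node and reports all candidates", {
  phy <- simulate_bd_tree(100, seed = 42)
  nodes <- candidate_nodes(phy, 0.25)
  hits <- 0L
  for (i in 1:12) {
    set.seed(300 + i)
    cl <- pick_shift_node(phy, "at_least_frac", 0.25)
    y <- simulate_traits(phy, model_spec("nested_EB", cl),
                         list(r = 0.9 * maxrate_r(), sigma2 = 1))
    sc <- scan_shift_nodes(phy, y, "nested_EB")
    expect_equal(nrow(sc$table), length(nodes))
    expect_equal(sc$best$AICc, min(sc$table$AICc))
    if (sc$best$node == cl$node) hits <- hits + 1L
  }
  expect_gt(hits, 6)  # majority recovery under a strong burst
})

test_that("a three-tip tree yields a single-candidate scan", {
  phy <- tree3()
  y <- c(A = 1, B = 0.5, C = -1)
  sc <- scan_shift_nodes(phy, y, "nested_shift", min_frac = 0.5)
  expect_equal(nrow(sc$table), 1L)
  expect_equal(sc$table$node, ape::getMRCA(phy, c("A", "B")))
})

test_that("penalty calibration is deterministic, bounded, and monotone", {
  phy <- simulate_bd_tree(25, seed = 17)
  p1 <- calibrate_penalties(phy, n_sims = 30, target_rate = 0.1, seed = 5)
  p2 <- calibrate_penalties(phy, n_sims = 30, target_rate = 0.1, seed = 5)
  expect_identical(p1$penalties, p2$penalties)
  expect_true(all(p1$penalties >= 0))
  expect_equal(unname(p1$penalties["BM"]), 0)
  # per-model AND final in-sample null rates bounded by the target
  expect_true(all(p1$model_error_rates <= 0.1))
  expect_lte(p1$null_error_rate, 0.1)

  # target rate 1 means no correction at all
  p_all <- calibrate_penalties(phy, n_sims = 30, target_rate = 1, seed = 5)
  expect_true(all(p_all$penalties == 0))

  # larger target rates never increase a penalty
  p_strict <- calibrate_penalties(phy, n_sims = 30, target_rate = 0.02, seed = 5)
  p_loose <- calibrate_penalties(phy, n_sims = 30, target_rate = 0.5, seed = 5)
  expect_true(all(p_loose$penalties <= p1$penalties + 1e-12))
  expect_true(all(p1$penalties <= p_strict$penalties + 1e-12))
})

test_that("model comparison applies penalties, ranks, and degrades gracefully", {
  phy <- simulate_bd_tree(60, seed = 23)
  set.seed(9)
  cl <- pick_shift_node(phy, "at_least_frac", 0.25)
  y <- simulate_traits(phy, model_spec("nested_EB", cl),
                       list(r = maxrate_r(), sigma2 = 1))
  sel <- compare_models(phy, y)
  expect_s3_class(sel, "model_selection")
  expect_true(sel$winner %in% c("nested_EB", "nested_EB_rate"))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_equal(sel$table$AICc_corrected, sel$table$AICc + sel$table$penalty)
  expect_equal(sel$table$model[which.min(sel$table$AICc_corrected)], sel$winner)

  # single-model set
  only_bm <- compare_models(phy, y, models = "BM")
  expect_equal(only_bm$winner, "BM")
  expect_equal(only_bm$table$weight, 1)

  # penalties must cover the model set
  expect_error(compare_models(phy, y, penalties = c(nested_EB = 2)), "missing")

  # identical inputs give identical output (no hidden randomness)
  expect_equal(compare_models(phy, y)$table, sel$table)
})

test_that("penalized comparison restores Brownian wins on Brownian data", {
  phy <- simulate_bd_tree(50, seed = 29)
  pen <- calibrate_penalties(phy, n_sims = 60, target_rate = 0.05, seed = 77)
  wins <- vapply(1:20, function(i) {
    y <- simulate_traits(phy, "BM", list(sigma2 = 1), seed = 4000 + i)
    compare_models(phy, y, penalties = pen)$winner
  }, character(1))
  expect_gte(mean(wins == "BM"), 0.8)
})
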