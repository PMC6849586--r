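test_that("early-burst segment lengths integrate the decaying rate", {
  expect_equal(eb_segment_length(0, 1, -1), 1 - exp(-1), tolerance = 1e-9)
  # stem: negative start time stretches the branch (the burst)
  expect_equal(eb_segment_length(-0.5, 0, -1), exp(0.5) - 1, tolerance = 1e-9)
  expect_gt(eb_segment_length(-0.5, 0, -1), 0.5)
  expect_equal(eb_segment_length(0, 1, -1e-12), 1)
  expect_error(eb_segment_length(0, 1, 0.1), "negative")

  # numerical-integration cross-check
  for (r in c(-0.3, -2, -9)) {
    num <- stats::integrate(function(t) exp(r * t), -0.4, 0.7)$value
    expect_equal(eb_segment_length(-0.4, 0.7, r), num, tolerance = 1e-7)
  }
})

test_that("nested transforms match closed-form branch integrals", {
  phy <- tree3()
  cl <- clade_selection(phy, ape::getMRCA(phy, c("A", "B")))
  Vp <- transform_vcv(phy, model_spec("nested_EB", cl), list(r = -1))
  expect_equal(Vp["A", "A"], (exp(1) - 1) + (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(Vp["A", "B"], exp(1) - 1, tolerance = 1e-9)
  expect_equal(Vp["C", "C"], 2)
  expect_equal(Vp["A", "C"], 0)

  Vs <- transform_vcv(phy, model_spec("nested_shift", cl), list(theta = 2))
  expect_equal(Vs["A", "A"], 4)
  expect_equal(Vs["A", "B"], 2)
  expect_equal(Vs["C", "C"], 2)
})

test_that("stated model collapses hold", {
  phy <- simulate_bd_tree(40, seed = 2)
  cl <- clade_selection(phy, candidate_nodes(phy, 0.25)[1])
  V <- vcv_shared_time(phy)

  expect_equal(transform_vcv(phy, model_spec("nested_EB_rate", cl),
                             list(r = -3, theta = 1)),
               transform_vcv(phy, model_spec("nested_EB", cl), list(r = -3)))
  expect_equal(transform_vcv(phy, model_spec("nested_shift", cl),
                             list(theta = 1)), V)
  # r -> 0- and alpha -> 0 limits recover plain Brownian motion
  for (spec in list(model_spec("EB"), model_spec("nested_EB", cl))) {
    expect_equal(transform_vcv(phy, spec, list(r = -1e-12)), V,
                 tolerance = 1e-6)
  }
  for (spec in list(model_spec("OU"), model_spec("nested_OU", cl))) {
    expect_equal(transform_vcv(phy, spec, list(alpha = 1e-12)), V,
                 tolerance = 1e-6)
  }
})

test_that("transformed matrices stay positive definite and leave V0 untouched", {
  set.seed(7)
  for (n in c(20, 80, 200)) {
    phy <- simulate_bd_tree(n, seed = n)
    cl <- clade_selection(phy, candidate_nodes(phy, 0.25)[1])
    V <- vcv_shared_time(phy)
    out <- setdiff(seq_len(n), cl$tip_idx)
    cases <- list(
      list(model_spec("EB"), list(r = -8)),
      list(model_spec("OU"), list(alpha = 2)),
      list(model_spec("nested_shift", cl), list(theta = 10)),
      list(model_spec("nested_OU", cl), list(alpha = 2)),
      list(model_spec("nested_EB", cl), list(r = -8)),
      list(model_spec("nested_EB_rate", cl), list(r = -8, theta = 10))
    )
    for (case in cases) {
      Vt <- transform_vcv(phy, case[[1]], case[[2]])
      expect_silent(chol(Vt))
      if (!is.null(case[[1]]$clade) && length(out)) {
        expect_equal(Vt[out, , drop = FALSE], V[out, , drop = FALSE])
      }
    }
  }
})

test_that("model specification validates parameters and clade requirements", {
  phy <- tree3()
  cl <- clade_selection(phy, ape::getMRCA(phy, c("A", "B")))
  expect_error(model_spec("nested_EB"), "require")
  expect_error(model_spec("BM", cl), "no shift clade")
  expect_error(transform_vcv(phy, model_spec("nested_EB", cl), list()), "requires")
  expect_error(transform_vcv(phy, model_spec("EB"), list(r = 0.5)), "negative")
  expect_error(transform_vcv(phy, model_spec("nested_EB_rate", cl),
                             list(r = -1, theta = 0.5)), "at least 1")
  # OU forms demand ultrametricity
  bad <- read_newick("((A:1,B:2):1,C:2);")
  expect_error(transform_vcv(bad, model_spec("OU"), list(alpha = 1)),
               class = "burstshift_not_ultrametric")
})
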