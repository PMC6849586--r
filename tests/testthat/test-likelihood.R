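test_that("GLS mean reduces to the plain mean on the identity and solves V", {
  expect_equal(gls_mean(diag(2), c(1, -1)), 0)
  expect_equal(gls_mean(diag(3), c(3, 3, 3)), 3)
  V <- vcv_shared_time(tree3())
  y <- c(A = 1, B = 1, C = 0)
  Vi <- solve(V)
  mu_direct <- drop(solve(t(rep(1, 3)) %*% Vi %*% rep(1, 3)) %*%
                      t(rep(1, 3)) %*% Vi %*% y)
  expect_equal(gls_mean(V, as.numeric(y[colnames(V)])), mu_direct,
               tolerance = 1e-12)
})

test_that("log-likelihood equals the exact multivariate-normal density", {
  expect_equal(trait_loglik(diag(2), c(0, 0), 1, 0), -log(2 * pi),
               tolerance = 1e-12)
  # rate/covariance rescaling identity
  V <- vcv_shared_time(tree3())
  y <- c(1, 1, 0)
  for (cc in c(0.3, 2, 7)) {
    expect_equal(trait_loglik(V, y, cc, 0.5), trait_loglik(cc * V, y, 1, 0.5),
                 tolerance = 1e-10)
  }
  mu <- gls_mean(V, y)
  s2 <- sigma2_estimate(V, y, mu, denominator = "n")
  expect_equal(trait_loglik(V, y, s2, mu), mvn_loglik_oracle(V, y, s2, mu),
               tolerance = 1e-10)
})

test_that("quadratic-form rate estimator handles both denominators", {
  V <- diag(2)
  y <- c(1, -1)
  expect_equal(sigma2_estimate(V, y, mu = 0, denominator = "n-1"), 2)
  expect_equal(sigma2_estimate(V, y, mu = 0, denominator = "n"), 1)
  expect_warning(s0 <- sigma2_estimate(diag(3), c(2, 2, 2)), "constant")
  expect_equal(s0, 0)
  expect_equal(sigma2_estimate(2 * V, y, mu = 0),
               sigma2_estimate(V, y, mu = 0) / 2)
})

test_that("AICc and Akaike weights follow their definitions", {
  expect_equal(aicc(-100, 3, 50), 206.521739, tolerance = 1e-6)
  expect_equal(aicc(-100, 2, 50), 204.255319, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "undefined")
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)

  expect_equal(unname(aicc_weights(c(100, 102))), c(0.731059, 0.268941),
               tolerance = 1e-6)
  expect_equal(unname(aicc_weights(c(5, 5, 5))), rep(1 / 3, 3))
  set.seed(1)
  expect_equal(sum(aicc_weights(runif(10, 100, 120))), 1)
})

test_that("fitting recovers the Brownian rate and respects model nesting", {
  phy <- simulate_bd_tree(200, seed = 4)
  s2 <- vapply(1:60, function(i) {
    y <- simulate_traits(phy, "BM", list(sigma2 = 1), seed = 1000 + i)
    fit_model(phy, y, "BM")$params$sigma2
  }, numeric(1))
  expect_lt(abs(mean(s2) - 1), 0.05)  # < 5% relative bias

  cl <- clade_selection(phy, candidate_nodes(phy, 0.25)[1])
  y <- simulate_traits(phy, model_spec("nested_EB", cl),
                       list(r = -6, sigma2 = 1), seed = 99)
  fits <- list(
    BM = fit_model(phy, y, "BM"),
    nested_shift = fit_model(phy, y, model_spec("nested_shift", cl)),
    nested_EB = fit_model(phy, y, model_spec("nested_EB", cl)),
    nested_EB_rate = fit_model(phy, y, model_spec("nested_EB_rate", cl))
  )
  # a richer model never fits worse than one it nests (optimizer tolerance)
  expect_gte(fits$nested_shift$logL, fits$BM$logL - 1e-4)
  expect_gte(fits$nested_EB_rate$logL, fits$nested_shift$logL - 1e-4)
  expect_gte(fits$nested_EB$logL, fits$BM$logL - 1e-4)
  expect_gte(fits$nested_EB_rate$logL, fits$nested_EB$logL - 1e-4)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
})

test_that("pinning the rate scalar at 1 collapses nested_EB_rate to nested_EB", {
  phy <- simulate_bd_tree(60, seed = 8)
  cl <- clade_selection(phy, candidate_nodes(phy, 0.25)[1])
  y <- simulate_traits(phy, model_spec("nested_EB", cl),
                       list(r = -5, sigma2 = 1), seed = 12)
  f_eb <- fit_model(phy, y, model_spec("nested_EB", cl))
  f_pin <- fit_model(phy, y, model_spec("nested_EB_rate", cl),
                     control = fit_control(fixed = list(theta = 1)))
  expect_equal(f_pin$logL, f_eb$logL, tolerance = 1e-6)
})

test_that("profiled and jointly optimized rate reach the same optimum", {
  phy <- simulate_bd_tree(50, seed = 14)
  cl <- clade_selection(phy, candidate_nodes(phy, 0.25)[1])
  y <- simulate_traits(phy, model_spec("nested_EB", cl),
                       list(r = -4, sigma2 = 1), seed = 5)
  for (spec in list(model_spec("BM"), model_spec("EB"),
                    model_spec("nested_EB", cl))) {
    f_prof <- fit_model(phy, y, spec)
    f_joint <- fit_model(phy, y, spec,
                         control = fit_control(profile_sigma2 = FALSE))
    expect_equal(f_prof$logL, f_joint$logL, tolerance = 1e-4)
    expect_equal(f_prof$params$sigma2, f_joint$params$sigma2, tolerance = 1e-2)
  }
})

test_that("AICc ordering is invariant to trait location shifts", {
  phy <- simulate_bd_tree(50, seed = 21)
  cl <- clade_selection(phy, candidate_nodes(phy, 0.25)[1])
  y <- simulate_traits(phy, model_spec("nested_EB", cl),
                       list(r = -6, sigma2 = 1), seed = 3)
  specs <- list(model_spec("BM"), model_spec("EB"),
                model_spec("nested_shift", cl), model_spec("nested_EB", cl))
  a1 <- vapply(specs, function(s) fit_model(phy, y, s)$AICc, numeric(1))
  a2 <- vapply(specs, function(s) fit_model(phy, y + 100, s)$AICc, numeric(1))
  expect_equal(order(a1), order(a2))
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("degenerate constant traits hit the rate's lower bound, flagged", {
  phy <- simulate_bd_tree(20, seed = 6)
  y <- stats::setNames(rep(1.5, 20), phy$tip.label)
  f <- fit_model(phy, y, "BM")
  expect_equal(f$params$sigma2, 1e-8)
  expect_equal(f$params$mu, 1.5, tolerance = 1e-8)
})
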