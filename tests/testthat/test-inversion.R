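test_that("inversion spec validates free parameters and bounds", {
  s <- inversion_spec("E")
  expect_equal(unname(s$lower), 0.01)
  expect_error(inversion_spec("E", lower = c(E = -1), upper = c(E = 50)),
               "positive")
  expect_error(inversion_spec("Rd"), "arg")
})

test_that("single-parameter inversion is exact on noiseless curves", {
  k <- cyls_k()
  truth <- leaf_parameters(E = 2.0)
  curve <- simulate_aci(seq(50, 1500, length.out = 12), k, truth)
  fit <- fit_leaf_parameters(curve, k, leaf_parameters(E = 10))
  expect_equal(coef(fit)[["E"]], 2.0, tolerance = 1e-6)
  expect_true(fit$converged)

  # kcat free with E fixed: forward-inverse round trip at the leaf-disc value
  k_gen <- k; k_gen$kcat <- 6.46
  truth2 <- leaf_parameters(E = 1.5)
  curve2 <- simulate_aci(seq(50, 1500, length.out = 12), k_gen, truth2)
  fit2 <- fit_leaf_parameters(curve2, k, truth2, inversion_spec("kcat"))
  expect_equal(coef(fit2)[["kcat"]], 6.46, tolerance = 1e-6)
})

test_that("round trip is exact for either single free parameter across values", {
  k <- cyls_k()
  for (E in c(0.5, 1.8, 8)) {
    curve <- simulate_aci(seq(50, 1500, length.out = 10), k,
                          leaf_parameters(E = E))
    expect_equal(coef(fit_leaf_parameters(curve, k, leaf_parameters(1)))[["E"]],
                 E, tolerance = 1e-6)
  }
})

test_that("inversion is unbiased over a noisy synthetic ensemble", {
  k <- cyls_k()
  E_gen <- 1.8
  ests <- vapply(1:200, function(i) {
    curve <- make_aci(k, leaf_parameters(E = E_gen), noise_sd = 0.25,
                      seed = 5000L + i)
    coef(fit_leaf_parameters(curve, k, leaf_parameters(E = 5)))[["E"]]
  }, numeric(1))
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - E_gen), 2 * mc_se + 1e-9)
})

test_that("jointly free E and kcat on purely Rubisco-limited data is unidentifiable", {
  k <- cyls_k()
  # grid above Gamma* so the Rubisco branch is the operative minimum throughout
  curve <- simulate_aci(seq(100, 1500, length.out = 12), k,
                        leaf_parameters(E = 1.8))
  expect_error(
    suppressWarnings(
      fit_leaf_parameters(curve, k, leaf_parameters(E = 5),
                          inversion_spec(c("E", "kcat")))),
    "unidentifiable")
  expect_warning(
    try(fit_leaf_parameters(curve, k, leaf_parameters(E = 5),
                            inversion_spec(c("E", "kcat"))), silent = TRUE),
    "weakly identified")
})

test_that("residual report is zero on exact curves and algebraic on offsets", {
  k <- cyls_k(); leaf <- cyls_leaf()
  grid <- seq(100, 2000, length.out = 9)
  curve <- simulate_aci(grid, k, leaf)
  rr <- residual_report(curve, k, leaf)
  expect_equal(rr$rmse, 0, tolerance = 1e-14)
  # +1 offset on one of n points: RMSE = 1/sqrt(n)
  A2 <- curve$A; A2[4] <- A2[4] + 1
  curve2 <- gas_exchange_curve(curve$Cc, A2)
  expect_equal(residual_report(curve2, k, leaf)$rmse, 1 / sqrt(9),
               tolerance = 1e-12)
})

test_that("residual RMSE estimates the generating noise level", {
  k <- cyls_k(); leaf <- cyls_leaf(1.8)
  rmses <- vapply(1:50, function(i) {
    curve <- make_aci(k, leaf, noise_sd = 0.25, seed = 100L + i,
                      Cc_grid = seq(50, 1500, length.out = 20))
    residual_report(curve, k, leaf)$rmse
  }, numeric(1))
  # mean RMSE within Monte-Carlo error of its expectation under the
  # generating noise: E[RMSE] ~ sigma (1 - 1/(4n)) for n = 20 points
  expected <- 0.25 * (1 - 1 / (4 * 20))
  mc_se <- stats::sd(rmses) / sqrt(length(rmses))
  expect_lt(abs(mean(rmses) - expected), 3 * mc_se)
})

test_that("standard error of the mean estimate shrinks as 1/sqrt(replicates)", {
  k <- cyls_k()
  ests <- vapply(1:80, function(i) {
    curve <- make_aci(k, leaf_parameters(E = 1.8), seed = 9000L + i)
    coef(fit_leaf_parameters(curve, k, leaf_parameters(E = 5)))[["E"]]
  }, numeric(1))
  se20 <- stats::sd(ests[1:20]) / sqrt(20)
  se80 <- stats::sd(ests) / sqrt(80)
  # quadrupling replicates roughly halves the SE of the mean
  expect_lt(se80, se20)
  expect_equal(se80 / se20, 0.5, tolerance = 0.5)
})
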