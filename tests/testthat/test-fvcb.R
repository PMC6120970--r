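test_that("gamma_star evaluates 0.5 O / S_C/O in ubar", {
  expect_equal(gamma_star(1e12), 0, tolerance = 1e-6)  # infinite-specificity limit
  expect_equal(gamma_star(2123, 200), 47.1, tolerance = 1e-3)
  expect_equal(gamma_star(1445, 200), 69.2, tolerance = 1e-3)
  expect_error(gamma_star(-5), "positive")
})

test_that("Rubisco-limited branch matches hand evaluation and saturates at kcat E - Rd", {
  k <- cyls_k(); leaf <- cyls_leaf()
  expect_equal(rubisco_limited_A(20000, k, leaf), 13.5, tolerance = 0.003)
  # saturation limit
  expect_equal(rubisco_limited_A(1e9, k, leaf), k$kcat * leaf$E - leaf$Rd,
               tolerance = 1e-4)
  # near-zero net assimilation at the tobacco compensation point
  kt <- tobacco_k(); lt <- tobacco_leaf()
  expect_equal(rubisco_limited_A(56.0, kt, lt), 0, tolerance = 0.01)
})

test_that("electron-limited branch has exact anchor points", {
  kt <- tobacco_k(); lt <- tobacco_leaf()
  gs <- gamma_star(kt$SCO, lt$O)
  # numerator vanishes at Gamma*: A = -Rd exactly
  expect_identical(electron_limited_A(gs, kt$SCO, lt), -lt$Rd)
  # large-Cc limit J/4 - Rd
  expect_equal(electron_limited_A(1e9, kt$SCO, lt), 140 / 4 - 1,
               tolerance = 1e-4)
  expect_equal(electron_limited_A(300, 2123, leaf_parameters(21.9)),
               21.45, tolerance = 1e-3)
})

test_that("model rejects unresolved molar-basis parameters", {
  k_molar <- genotype_kinetics("CyLS")
  expect_error(rubisco_limited_A(300, k_molar, cyls_leaf()), "basis")
  expect_error(net_A(300, k_molar, cyls_leaf()), "basis")
})

test_that("net assimilation is the pointwise minimum and both branches increase in Cc", {
  k <- cyls_k(); leaf <- cyls_leaf()
  cc <- seq(0, 20000, length.out = 200)
  ac <- rubisco_limited_A(cc, k, leaf)
  aj <- electron_limited_A(cc, k$SCO, leaf)
  an <- net_A(cc, k, leaf)
  expect_true(all(an <= ac + 1e-12) && all(an <= aj + 1e-12))
  expect_equal(an, pmin(ac, aj))
  expect_true(all(diff(ac) > 0))
  expect_true(all(diff(aj) > 0))
  # the high-CO2 point is Rubisco-limited for this preparation
  expect_equal(net_A(20000, k, leaf), 13.5, tolerance = 0.003)
  expect_gt(electron_limited_A(20000, k$SCO, leaf), 30)
})

test_that("compensation point matches printed values for both reference preparations", {
  g_tob <- compensation_point(tobacco_k(), tobacco_leaf())
  expect_equal(g_tob, 56.0, tolerance = 0.002)
  expect_equal(g_tob, 55, tolerance = 0.02)  # printed 55 +/- 1
  g_cyls <- compensation_point(cyls_k(), cyls_leaf())
  expect_equal(g_cyls, 492.5, tolerance = 0.002)
  expect_equal(g_cyls, 503, tolerance = 0.03)  # printed 503 +/- 69
})

test_that("closed-form compensation point has its limits and failure modes", {
  k <- cyls_k()
  # Rd = 0 collapses Gamma to Gamma*
  leaf0 <- leaf_parameters(E = 2.1, Rd = 0)
  expect_equal(compensation_point(k, leaf0), gamma_star(k$SCO, leaf0$O),
               tolerance = 1e-12)
  # no root when respiration exceeds carboxylation capacity
  expect_error(compensation_point(k, leaf_parameters(E = 0.05, Rd = 1)),
               "compensation")
})

test_that("closed-form Gamma agrees with a bisection root of net_A across a parameter sweep", {
  set.seed(7)
  for (i in 1:40) {
    kcat <- stats::runif(1, 1, 12)
    E <- stats::runif(1, 1, 30)
    KC <- stats::runif(1, 300, 10000)
    SCO <- stats::runif(1, 1000, 3000)
    k <- rubisco_kinetics(kcat = kcat, KC_21O2 = KC, SCO = SCO,
                          basis = "ubar", sco_basis = "pressure")
    leaf <- leaf_parameters(E = E)
    gamma <- suppressWarnings(compensation_point(k, leaf))
    upper <- 1000
    while (net_A(upper, k, leaf) < 0) upper <- upper * 2
    root <- stats::uniroot(function(cc) net_A(cc, k, leaf),
                           lower = 0, upper = upper, tol = 1e-9)$root
    expect_equal(gamma, root, tolerance = 1e-6)
  }
})

test_that("simulated curves are consistent with the model and linear in E below saturation", {
  k <- cyls_k(); leaf <- cyls_leaf()
  grid <- seq(100, 20000, length.out = 30)
  curve <- simulate_aci(grid, k, leaf)
  expect_s3_class(curve, "gas_exchange_curve")
  expect_equal(curve$A[nrow(curve)], net_A(20000, k, leaf), tolerance = 1e-12)
  # A crosses zero at the compensation point
  gamma <- compensation_point(k, leaf)
  expect_equal(net_A(gamma, k, leaf), 0, tolerance = 1e-9)
  # doubling E doubles A + Rd wherever Rubisco-limited
  leaf2 <- leaf_parameters(E = 2 * leaf$E)
  cc <- c(200, 1000, 5000)
  expect_equal(rubisco_limited_A(cc, k, leaf2) + leaf2$Rd,
               2 * (rubisco_limited_A(cc, k, leaf) + leaf$Rd),
               tolerance = 1e-12)
})

test_that("gas_exchange_curve validates and records provenance", {
  expect_error(gas_exchange_curve(c(1, 2, 3), c(1, 2, 3)), "4 points")
  expect_error(gas_exchange_curve(c(-1, 2, 3, 4), 1:4), "non-negative")
  cv <- gas_exchange_curve(c(4, 2, 3, 1), c(40, 20, 30, 10),
                           supplied_as = "Ci")
  expect_equal(cv$Cc, 1:4)  # sorted ascending
  expect_equal(cv$A, c(10, 20, 30, 40))
  expect_identical(attr(cv, "supplied_as"), "Ci")
})
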