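test_that("rubisco_kinetics validates its invariants", {
  expect_error(rubisco_kinetics(kcat = -1, KC_21O2 = 100), "positive")
  expect_error(rubisco_kinetics(kcat = 1, KC_21O2 = 100, KC_N2 = 150),
               "competitive")
  k <- rubisco_kinetics(kcat = 9.8, KC_21O2 = 275, KC_N2 = 158, SCO = 55)
  expect_s3_class(k, "rubisco_kinetics")
  expect_identical(k$basis, "uM")
})

test_that("resolve_to_pressure converts bases once and is idempotent", {
  k <- cyls_k()
  expect_identical(k$basis, "ubar")
  expect_identical(k$sco_basis, "pressure")
  expect_equal(k$KC_21O2, 275 / 0.0334, tolerance = 1e-12)
  expect_equal(resolve_to_pressure(k), k)
})

test_that("Michaelis-Menten fit recovers generating parameters exactly on noiseless data", {
  S <- assay_design_grid("CO2")
  fit <- fit_michaelis_menten(mm_series(10, 158, S))
  expect_equal(unname(coef(fit)), c(10, 158), tolerance = 1e-6)
  expect_true(fit$converged)
  # half-maximal rate at S = Km on the fitted curve
  p <- coef(fit)
  expect_equal(p[["Vmax"]] * p[["Km"]] / (p[["Km"]] + p[["Km"]]),
               p[["Vmax"]] / 2, tolerance = 1e-12)
})

test_that("noiseless recovery holds across the (Vmax, Km) plane", {
  set.seed(42)
  for (i in 1:12) {
    Vmax <- 10^stats::runif(1, -1, 3)
    Km <- 10^stats::runif(1, -1, 3)
    S <- Km * c(0.2, 0.5, 1, 2, 5, 10)
    fit <- fit_michaelis_menten(mm_series(Vmax, Km, S))
    expect_equal(unname(coef(fit)), c(Vmax, Km), tolerance = 1e-6)
  }
})

test_that("fit is unbiased for Km on noisy replicate ensembles", {
  # 200 replicates at 5% CV around the free-Rubisco Km
  S <- assay_design_grid("CO2")
  k <- rubisco_kinetics(kcat = 9.4, KC_21O2 = 169, label = "free")
  kms <- vapply(1:200, function(i) {
    d <- make_assay(k, site_content = 1.5, cv = 0.05, seed = 1000L + i)
    coef(fit_michaelis_menten(d))[["Km"]]
  }, numeric(1))
  mc_se <- stats::sd(kms) / sqrt(length(kms))
  expect_lt(abs(mean(kms) - 169), 2 * mc_se + 1e-9)
})

test_that("fit rejects degenerate designs", {
  expect_error(assay_dataset(c(100, 100, 100), c(1, 2, 3)), "equal")
  expect_error(
    fit_michaelis_menten(data.frame(conc = c(1, 1, 2), rate = c(1, 1, 2))),
    "distinct")
})

test_that("kcat is Vmax over site content, linear and scale-inverse", {
  expect_identical(kcat_from_vmax(0, 5), 0)
  expect_equal(kcat_from_vmax(67.89, 21.9), 3.10, tolerance = 1e-3)
  expect_equal(kcat_from_vmax(20.58, 2.1), 9.8, tolerance = 1e-3)
  expect_equal(kcat_from_vmax(2 * 20.58, 2.1), 2 * 9.8, tolerance = 1e-3)
  expect_equal(kcat_from_vmax(20.58, 2 * 2.1), 9.8 / 2, tolerance = 1e-3)
  expect_error(kcat_from_vmax(10, 0), "positive")
})

test_that("KO inference inverts the competitive-inhibition model", {
  expect_identical(infer_KO(100, 100, 252), Inf)
  # dissolved O2 at the assay: 200 mbar x 0.00126 M bar^-1 ~ 252 uM
  expect_equal(infer_KO(9.7, 18.3, 252), 284.2, tolerance = 1e-3)
  expect_equal(infer_KO(158, 275, 252), 340.3, tolerance = 1e-3)
  expect_error(infer_KO(275, 158, 252), "inconsistent")
  # round trip: KC_app = KC (1 + O/KO) reproduces the input
  KO <- infer_KO(158, 275, 252)
  expect_equal(158 * (1 + 252 / KO), 275, tolerance = 1e-12)
})

test_that("specificity from product ratio honours the stoichiometry mode", {
  # PGA/PG = 3 => vc/vo = 1; with O/C = 1 the specificity is 1
  expect_equal(as.numeric(sco_from_product_ratio(3, 1, 100, 100)), 1)
  # invert the tobacco pressure-basis value through the default mode
  s <- sco_from_product_ratio(1 + 2 * 1.0620, 1, 500, 999500)
  expect_equal(as.numeric(s), 2123, tolerance = 0.002)
  expect_identical(attr(s, "basis"), "pressure")
  # direct mode takes the ratio as vc/vo unchanged
  expect_equal(as.numeric(
    sco_from_product_ratio(2, 1, 500, 999500, "direct")), 2 * 1999)
  expect_error(sco_from_product_ratio(0.9, 1, 500, 999500), "ratio")
})
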