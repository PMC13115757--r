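test_that("noiseless linear diagram is classified A_L with exact slope", {
  dg <- synth_solubility(K = 54, S0 = 7.7e-6)
  cl <- classify_diagram(dg)
  expect_identical(cl$type, "A_L")
  expect_equal(cl$slope, attr(dg, "truth")$slope, tolerance = 1e-9)
  expect_equal(cl$intercept, 7.7e-6, tolerance = 1e-9)
})

test_that("stability constant round trip recovers the generating K", {
  for (K in c(54, 208)) {
    dg <- synth_solubility(K = K, S0 = 2e-6,
                           pH = if (K == 208) 3.5 else 7.4)
    cl <- classify_diagram(dg)
    expect_identical(cl$type, "A_L")
    expect_lt(abs(stability_constant(cl$slope, cl$intercept) - K) / K,
              0.005)
  }
})

test_that("curved and plateauing diagrams get A_P and B calls", {
  # strong positive quadratic component
  dgp <- synth_solubility(K = 54, S0 = 7.7e-6, curvature = 0.4,
                          sigma_frac = 0.005, seed = 60)
  expect_identical(classify_diagram(dgp)$type, "A_P")
  # plateau then decline at high cyclodextrin
  cd <- seq(0, 14e-3, length.out = 10)
  y <- pmin(7.7e-6 + 4e-4 * cd, 9.5e-6)
  y[9:10] <- y[9:10] * c(0.98, 0.94)
  dgb <- solubility_diagram(cd, y)
  expect_identical(classify_diagram(dgb)$type, "B")
})

test_that("stability constant follows hand-calculated cases and bounds", {
  expect_equal(stability_constant(0.5, 1e-4), 1e4)
  # vanishing slope gives vanishing K
  expect_lt(stability_constant(1e-8, 1e-4), 1e-3)
  # monotone increasing in slope, decreasing in S0
  expect_gt(stability_constant(0.6, 1e-4), stability_constant(0.5, 1e-4))
  expect_gt(stability_constant(0.5, 1e-4), stability_constant(0.5, 2e-4))
  expect_error(stability_constant(1.2, 1e-4), "invalid")
  expect_error(stability_constant(-0.1, 1e-4), "positive")
})

test_that("solubility enhancement reproduces the reported fold factors", {
  # saturation concentrations with / without cyclodextrin at pH 7.4
  expect_identical(solubility_enhancement(4.6e-5, 7.7e-6, "nearest_int"),
                   6)
  expect_equal(solubility_enhancement(4.6e-5, 7.7e-6), 4.6e-5 / 7.7e-6)
  expect_equal(solubility_enhancement(2e-5, 2e-5), 1)
  expect_error(solubility_enhancement(0, 1e-5), "positive")
})
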