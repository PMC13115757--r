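test_that("van't Hoff regression recovers generating parameters exactly", {
  # enthalpy-driven PBS-like parameter set over the 5-45 C design
  Tk <- seq(278.15, 318.15, by = 10)
  fit <- vant_hoff_fit(Tk, vant_hoff_K(Tk, dH = -26.2, dS = -56.1))
  expect_equal(fit$dH, -26.2, tolerance = 1e-9)
  expect_equal(fit$dS, -56.1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # Gibbs identity and K round trip
  expect_equal(dG_at(fit, 298.15), -26.2 - 298.15 * (-56.1) / 1000,
               tolerance = 1e-12)
  expect_equal(predict_K(fit, Tk), vant_hoff_K(Tk, -26.2, -56.1),
               tolerance = 1e-9)
})

test_that("temperature-independent K gives dH = 0 and dS = R ln K", {
  Tk <- c(280, 290, 300, 310)
  fit <- vant_hoff_fit(Tk, rep(150, 4))
  expect_equal(fit$dH, 0, tolerance = 1e-10)
  expect_equal(fit$dS, 8.314 * log(150), tolerance = 1e-9)
})

test_that("two-temperature input interpolates exactly with zero residual", {
  fit <- vant_hoff_fit(c(280, 310), c(120, 60))
  expect_equal(predict_K(fit, 280), 120, tolerance = 1e-9)
  expect_equal(predict_K(fit, 310), 60, tolerance = 1e-9)
  expect_identical(unname(fit$std_errors), c(0, 0))
})

test_that("entropy-only binding predicts the hand-calculated constant", {
  # dH = 0, dS = +38.6 J/K/mol (lactone-form citrate conditions):
  # K = exp(38.6 / 8.314) at any temperature
  fit <- vant_hoff_fit(c(280, 300), vant_hoff_K(c(280, 300), 0, 38.6))
  expect_equal(predict_K(fit, 298.15), exp(38.6 / 8.314),
               tolerance = 1e-9)
  expect_equal(predict_K(fit, 298.15), 103.9, tolerance = 1e-3)
  # dG = 0 gives K = 1
  fit0 <- vant_hoff_fit(c(280, 300), c(1, 1))
  expect_equal(predict_K(fit0, 298.15), 1, tolerance = 1e-12)
})

test_that("degenerate inputs are handled with warnings or errors", {
  expect_warning(vant_hoff_fit(c(280, 280, 300), c(100, 110, 60)),
                 "duplicate")
  expect_error(vant_hoff_fit(c(280, 300), c(-1, 60)), "positive")
  expect_error(vant_hoff_fit(300, 100), "length")
})
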