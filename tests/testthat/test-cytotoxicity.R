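test_that("survival percentages follow the absorbance ratio", {
  expect_equal(survival_percent(0.6, 0.6), 100)
  expect_equal(survival_percent(0, 0.6), 0)
  expect_equal(survival_percent(0.30, 0.60), 50)
  expect_error(survival_percent(0.3, 0), "positive")
})

test_that("noiseless 4PL data give exact IC50 recovery", {
  dr <- synth_mtt(ic50 = 17e-9, hill = 1.5, bottom = 5, sigma = 0)
  fit <- fit_ic50(dr)
  expect_equal(fit$ic50, 17e-9, tolerance = 1e-6)
  expect_equal(fit$hill, 1.5, tolerance = 1e-4)
  expect_equal(fit$bottom, 5, tolerance = 1e-3)
  # survival at the fitted IC50 is the asymptote midpoint
  expect_equal(predict(fit, fit$ic50), (100 + fit$bottom) / 2,
               tolerance = 1e-6)
})

test_that("IC50 estimation is scale-equivariant in dose", {
  dr <- synth_mtt(ic50 = 17e-9, sigma = 5, seed = 80)
  fit1 <- fit_ic50(dr)
  dr2 <- dose_response(dr$dose * 1e3, dr$survival, dr$cell_line,
                       dr$treatment, dr$exposure_h)
  fit2 <- fit_ic50(dr2)
  expect_equal(fit2$ic50 / fit1$ic50, 1e3, tolerance = 1e-6)
})

test_that("survival curves that never cross 50% are refused", {
  dr <- dose_response(c(0, 1e-9, 2e-9, 5e-9, 1e-8),
                      matrix(rep(c(100, 99, 98, 97, 96), 3), ncol = 3))
  expect_error(fit_ic50(dr), "50%")
})

test_that("triplicate noisy plates recover IC50 within 20% most of the time", {
  set.seed(81)
  ok <- replicate(200, {
    dr <- synth_mtt(ic50 = 17e-9, sigma = 5)
    fit <- fit_ic50(dr)
    abs(fit$ic50 - 17e-9) / 17e-9 < 0.20
  })
  expect_gte(mean(ok), 0.90)
})

test_that("replicate-level IC50 comparison behaves like Student's t-test", {
  a <- c(17e-9, 18e-9, 16e-9)
  # identical groups: t = 0, p = 1
  same <- compare_ic50(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # well-separated groups are detected
  b <- a * 3
  expect_true(compare_ic50(a, b)$significant)
  # swapping groups negates t and leaves p unchanged
  ab <- compare_ic50(a, b); ba <- compare_ic50(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  # matches the reference implementation on the log scale
  ref <- t.test(log(a), log(b), var.equal = TRUE)
  expect_equal(ab$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ab$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("per-replicate fits feed the comparison", {
  fa <- fit_ic50(synth_mtt(ic50 = 17e-9, sigma = 4, seed = 82),
                 per_replicate = TRUE)
  fb <- fit_ic50(synth_mtt(ic50 = 60e-9, sigma = 4, seed = 83),
                 per_replicate = TRUE)
  expect_length(fa$ic50_replicates, 3)
  cmp <- compare_ic50(fa, fb)
  expect_true(cmp$significant)
})
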