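test_that("linear Stern-Volmer series gives the hand-calculated k_q", {
  s <- synth_quench(K_SV = 120, tau0 = 4.2)
  sv <- stern_volmer_fit(s)
  expect_equal(sv$K_SV, 120, tolerance = 1e-9)
  # k_q = 120 / 4.2e-9 s
  expect_equal(sv$k_q, 120 / 4.2e-9, tolerance = 1e-9)
  expect_equal(sv$k_q, 2.857e10, tolerance = 1e-3)
  expect_true(all(sv$linear_mask))
})

test_that("intensity and lifetime ratios agree for purely dynamic quenching", {
  s <- synth_quench(K_SV = 85, tau0 = 3.7, sigma = 0.002, seed = 50)
  ki <- stern_volmer_fit(s, "intensity")$K_SV
  kt <- stern_volmer_fit(s, "lifetime")$K_SV
  expect_lt(abs(ki - kt) / kt, 0.01)
})

test_that("linear-region mask excludes the curved high-quencher tail", {
  s <- synth_quench(K_SV = 120, curvature = 1.5e5, sigma = 0.005,
                    seed = 51)
  sv <- stern_volmer_fit(s, "intensity")
  expect_lt(sv$n_linear, nrow(s))           # tail excluded
  expect_lt(abs(sv$K_SV - 120) / 120, 0.05) # dynamic slope recovered
  # the lifetime ratio of the same series stays linear throughout
  svt <- stern_volmer_fit(s, "lifetime")
  expect_lt(abs(svt$K_SV - 120) / 120, 0.05)
})

test_that("series curved from the origin falls back to the first 4 points", {
  q <- seq(0, 0.02, length.out = 10)
  y <- 1 + 120 * q + 4e4 * q^1.5  # strongly non-linear from the start
  s <- quench_series(q, intensity_ratio = y, tau0 = 4.2)
  expect_warning(sv <- stern_volmer_fit(s), "curvature")
  expect_identical(sv$n_linear, 4L)
})

test_that("quench series validation enforces unit ratio at zero quencher", {
  expect_error(quench_series(c(0, 0.01), intensity_ratio = c(1.2, 2),
                             tau0 = 4.2), "zero quencher")
  expect_error(quench_series(c(0.005, 0.01), intensity_ratio = c(1, 2),
                             tau0 = 4.2), "zero-quencher")
  expect_error(quench_series(c(0, 0.01), intensity_ratio = c(1, 0.5),
                             tau0 = 4.2), "below 1")
})
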