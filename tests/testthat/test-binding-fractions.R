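test_that("1:1 bound fraction reproduces hand-calculated cases", {
  # no binding
  expect_equal(complex_fraction_1to1(0, 1e-6, 5e-3), 0)
  expect_equal(complex_fraction_1to1(0, host_total = 5e-3,
                                     mode = "host_excess"), 0)
  # K*H = 1 gives half-saturation in the host-excess limit
  expect_equal(complex_fraction_1to1(200, host_total = 5e-3,
                                     mode = "host_excess"), 0.5)
  # exact solver agrees with the host-excess form for uM guest vs mM host
  f_ex <- complex_fraction_1to1(200, 1e-6, 5e-3, "exact")
  expect_lt(abs(f_ex - 0.5) / 0.5, 1e-3)
  # and with the independent bisection oracle
  expect_equal(f_ex, fraction_oracle_1to1(200, 1e-6, 5e-3),
               tolerance = 1e-10)
})

test_that("exact 1:1 solver matches the bisection oracle on a random grid", {
  set.seed(101)
  for (i in 1:200) {
    K <- 10^runif(1, 0, 5)
    G <- 10^runif(1, -7, -3)
    H <- 10^runif(1, -6, -1)
    f <- complex_fraction_1to1(K, G, H, "exact")
    expect_lt(abs(f - fraction_oracle_1to1(K, G, H)), 1e-9)
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("host-excess approximation holds when host >= 100x guest", {
  set.seed(102)
  for (i in 1:100) {
    K <- 10^runif(1, 0, 4)
    H <- 10^runif(1, -5, -2)
    G <- H / 10^runif(1, 2, 4)  # at least 100-fold excess
    f_ex <- complex_fraction_1to1(K, G, H, "exact")
    f_hx <- complex_fraction_1to1(K, host_total = H, mode = "host_excess")
    expect_lt(abs(f_ex - f_hx) / max(f_hx, 1e-12), 0.005)
  }
})

test_that("1:2 bound fraction follows the overall mass-action form", {
  expect_equal(complex_fraction_1to2(0, 1e-3), 0)
  # half-saturation at H = K^(-1/2) by construction
  expect_equal(complex_fraction_1to2(1e8, 1e-4), 0.5)
  expect_equal(complex_fraction_1to2(1e8, 1e-3), 100 / 101)
  # monotone nondecreasing in host
  h <- 10^seq(-6, -1, length.out = 50)
  expect_true(all(diff(complex_fraction_1to2(5e4, h)) >= 0))
})

test_that("fraction solvers reject unphysical inputs", {
  expect_error(complex_fraction_1to1(-1, 1e-6, 1e-3), "non-negative")
  expect_error(complex_fraction_1to1(10, 1e-6, -1e-3), "non-negative")
  expect_error(complex_fraction_1to1(10, 0, 1e-3, "exact"), "positive")
  expect_error(complex_fraction_1to2(-5, 1e-3), "non-negative")
  expect_error(complex_fraction_1to2(5, -1e-3), "non-negative")
})
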