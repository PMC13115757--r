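test_that("L-format anisotropy reproduces limiting and hand cases", {
  expect_equal(anisotropy_from_intensities(2, 1, 1), 0.25)
  # fully depolarized: I_VV = G I_VH
  expect_equal(anisotropy_from_intensities(1.7, 1, 1.7), 0)
  # no perpendicular component
  expect_equal(anisotropy_from_intensities(5, 0, 1), 1)
  expect_error(anisotropy_from_intensities(0, 0, 1), "zero total")
  expect_error(anisotropy_from_intensities(-1, 2, 1), "non-negative")
})

test_that("anisotropy computation inverts the polarized-intensity split", {
  set.seed(5)
  for (i in 1:50) {
    r <- runif(1, -0.1, 0.4)
    G <- runif(1, 0.5, 2)
    total <- runif(1, 1e3, 1e6)
    p <- polarized_intensities(r, total, G)
    expect_equal(anisotropy_from_intensities(p$I_VV, p$I_VH, G), r,
                 tolerance = 1e-12)
  }
})

test_that("weighted mean lifetime is an amplitude-weighted second moment", {
  expect_equal(weighted_mean_lifetime(1, 4.2), 4.2)
  expect_equal(weighted_mean_lifetime(c(0.5, 0.5), c(2, 4)), 10 / 3)
  # homogeneous of degree zero in the amplitudes
  expect_equal(weighted_mean_lifetime(c(5, 5), c(2, 4)),
               weighted_mean_lifetime(c(0.5, 0.5), c(2, 4)))
  # always bounded by the component lifetimes
  set.seed(6)
  for (i in 1:50) {
    A <- runif(3)
    tau <- runif(3, 0.1, 20)
    m <- weighted_mean_lifetime(A, tau)
    expect_gte(m, min(tau))
    expect_lte(m, max(tau))
  }
  expect_error(weighted_mean_lifetime(c(0, 0), c(1, 2)), "zero")
  expect_error(weighted_mean_lifetime(1, c(1, 2)), "length")
})

test_that("emission peak location resolves the lactone-carboxylate shift", {
  lact <- synth_emission_spectrum(431)
  carb <- synth_emission_spectrum(445)
  expect_equal(peak_wavelength(lact$wavelength, lact$intensity), 431,
               tolerance = 0.1)
  expect_equal(emission_shift(lact, carb), 14, tolerance = 0.2)
})
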