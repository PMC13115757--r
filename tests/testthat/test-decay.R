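test_that("noiseless mono-exponential decay is recovered to <0.1%", {
  tr <- synth_decay(lifetimes = 4.2, peak_counts = 1e4, noise = "none")
  fit <- fit_decay(tr, 1)
  expect_lt(abs(fit$lifetimes - 4.2) / 4.2, 1e-3)
  expect_equal(fit$mean_lifetime, fit$lifetimes)  # single component
})

test_that("Poisson-noised decay at 10k peak counts fits within 2%", {
  tr <- synth_decay(lifetimes = 4.2, peak_counts = 1e4,
                    noise = "poisson", seed = 40)
  fit <- fit_decay(tr, 1)
  expect_lt(abs(fit$lifetimes - 4.2) / 4.2, 0.02)
  expect_gt(fit$chisq_reduced, 0.8)
  expect_lt(fit$chisq_reduced, 1.2)
})

test_that("noiseless bi-exponential components are resolved", {
  tr <- synth_decay(amplitudes = c(0.6, 0.4), lifetimes = c(1.5, 6),
                    peak_counts = 2e4, noise = "none")
  fit <- fit_decay(tr, 2)
  expect_equal(fit$lifetimes, c(1.5, 6), tolerance = 0.01)
  # mean lifetime consistent with the standalone definition
  expect_equal(fit$mean_lifetime,
               weighted_mean_lifetime(fit$amplitudes, fit$lifetimes))
})

test_that("IRF reconvolution recovers the lifetime of a convolved trace", {
  # build a convolved histogram from a Gaussian instrument response
  n <- 1024
  tt <- seq(0, 100, length.out = n + 1)[-(n + 1)]
  irf <- exp(-0.5 * ((tt - 5) / 0.4)^2)
  imp <- exp(-tt / 4.2)
  mu <- convolve(imp, rev(irf / sum(irf)), type = "open")[1:n]
  counts <- round(5 + mu / max(mu) * 1e4)
  tr <- decay_trace(tt, counts, irf = round(irf * 1e4))
  fit <- fit_decay(tr, 1, reconvolve = TRUE)
  expect_lt(abs(fit$lifetimes - 4.2) / 4.2, 0.02)
})

test_that("background-only trace is rejected", {
  set.seed(41)
  tt <- seq(0, 100, length.out = 1024 + 1)[-1025]
  tr <- decay_trace(tt, rpois(1024, 10))
  expect_error(fit_decay(tr, 1), "background")
})

test_that("decay container enforces integer counts and uniform spacing", {
  expect_error(decay_trace(c(0, 1, 2), c(1.5, 2, 3)), "integers")
  expect_error(decay_trace(c(0, 1, 3), c(1, 2, 3)), "uniform")
  expect_error(decay_trace(c(0, 1, 2), c(1, -2, 3)), "integers")
})
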