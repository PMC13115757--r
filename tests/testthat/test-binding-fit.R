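test_that("anisotropy prediction honours its limiting cases", {
  fit <- fit_binding_isotherm(
    synth_titration(K = 200, r_free = 0.005, r_inf = 0.047, sigma_r = 0),
    "1:1")
  # zero host returns r_free exactly; large host approaches r_inf
  expect_identical(predict(fit, 0), fit$r_free)
  expect_equal(predict(fit, 1e3), fit$r_inf, tolerance = 1e-4)
  # half-bound point is the midpoint anisotropy: 0.026 for the citrate
  # parameter set (r_free 0.005, r_inf 0.047)
  expect_equal(predict(fit, 1 / fit$K), 0.026, tolerance = 1e-6)
})

test_that("predicted anisotropy is monotone nondecreasing in host", {
  set.seed(11)
  for (i in 1:20) {
    tit <- synth_titration(K = 10^runif(1, 1, 3), sigma_r = 1e-3)
    fit <- fit_quiet(tit, "1:1")
    h <- seq(0, 0.05, length.out = 100)
    expect_true(all(diff(predict(fit, h)) >= -1e-12))
  }
})

test_that("noiseless 1:1 round trip recovers all parameters to <0.1%", {
  tit <- synth_titration(K = 200, r_free = 0.005, r_inf = 0.047,
                         host_max = 14e-3, n_points = 12, sigma_r = 0)
  fit <- fit_binding_isotherm(tit, "1:1")
  expect_lt(abs(fit$K - 200) / 200, 1e-3)
  expect_lt(abs(fit$r_free - 0.005) / 0.005, 1e-3)
  expect_lt(abs(fit$r_inf - 0.047) / 0.047, 1e-3)
  # noiseless 1:2 round trip as well, including the K^1/2 invariant
  t12 <- synth_titration(K = 5e4, stoichiometry = "1:2", sigma_r = 0)
  f12 <- fit_binding_isotherm(t12, "1:2")
  expect_lt(abs(f12$K - 5e4) / 5e4, 1e-3)
  expect_equal(f12$K_sqrt^2, f12$K, tolerance = 1e-9)
})

test_that("seeded noisy fit covers the true K with its Wald interval", {
  tit <- synth_titration(K = 200, host_max = 14e-3, sigma_r = 1e-3,
                         seed = 20)
  fit <- fit_quiet(tit, "1:1")
  half <- qt(0.975, fit$df_residual) * fit$std_errors[["K"]]
  expect_gt(200, fit$K - half)
  expect_lt(200, fit$K + half)
})

test_that("flat anisotropy series is flagged as unidentifiable", {
  tit <- titration(seq(0, 12e-3, length.out = 8), rep(0.010, 8),
                   298.15, "PBS_pH7.4", 1e-6)
  cond <- tryCatch(fit_binding_isotherm(tit, "1:1"),
                   warning = function(w) w, error = function(e) e)
  expect_true(inherits(cond, "warning") || inherits(cond, "error"))
})

test_that("double-reciprocal fit matches the nonlinear fit on clean data", {
  tit <- synth_titration(K = 200, r_free = 0.005, r_inf = 0.047,
                         sigma_r = 0)
  lin <- linearized_fit_1to1(tit)
  nl <- fit_binding_isotherm(tit, "1:1")
  expect_lt(abs(lin$K - nl$K) / nl$K, 1e-3)
  expect_equal(lin$R2, 1, tolerance = 1e-9)
  # three-point minimal series (zero point + two transformed points):
  # the regression passes exactly through both points
  tit3 <- titration(c(0, 2e-3, 8e-3),
                    predict_anisotropy_params(150, 0.006, 0.05,
                                              c(0, 2e-3, 8e-3)),
                    298.15, "citrate_pH3.5", 1e-6)
  lin3 <- linearized_fit_1to1(tit3)
  expect_equal(lin3$K, 150, tolerance = 1e-9)
  expect_equal(lin3$R2, 1, tolerance = 1e-12)
})

test_that("linearized 1:1 fit degrades on 1:2-generated data", {
  # host window above the half-saturation, where the double-reciprocal
  # transform of sigmoidal data stays computable
  h <- c(0, seq(6e-3, 12e-3, length.out = 8))
  r <- predict_anisotropy_params(5e4, 0.005, 0.05, h, "1:2")
  t12 <- titration(h, r, 298.15, "PBS_pH7.4", 1e-6)
  lin <- suppressMessages(linearized_fit_1to1(t12))
  f12 <- fit_binding_isotherm(t12, "1:2")
  # the mismatched hyperbolic model leaves an order of magnitude more
  # residual variance than the generating sigmoidal model
  expect_gt(lin$residual_ss, 10 * f12$residual_ss)
  # on the full sigmoid the transform is inconsistent with a rising
  # 1:1 isotherm and is refused outright
  full <- synth_titration(K = 5e4, stoichiometry = "1:2", sigma_r = 0)
  expect_error(suppressMessages(linearized_fit_1to1(full)),
               "inconsistent")
})

test_that("points below r_free are excluded from the linearized fit", {
  h <- seq(0, 12e-3, length.out = 8)
  r <- predict_anisotropy_params(200, 0.01, 0.05, h)
  r[2] <- 0.009  # dips below the zero-host anisotropy
  tit <- titration(h, r, 298.15, "PBS_pH7.4", 1e-6)
  expect_message(linearized_fit_1to1(tit), "excluded")
})

test_that("stoichiometry selection identifies the generating model", {
  # seeded single-dataset cases at realistic noise
  t11 <- synth_titration(K = 200, n_points = 12, sigma_r = 1e-3, seed = 31)
  expect_identical(select_quiet(t11)$selected, "1:1")
  # strong 1:2 complex titrated across its half-saturation (0.1 mM)
  t12 <- synth_titration(K = 1e8, stoichiometry = "1:2",
                         host_max = 1.2e-3, sigma_r = 1e-3, seed = 32)
  expect_identical(select_quiet(t12)$selected, "1:2")
  # noiseless data separate the models by a wide criterion gap
  s11 <- select_quiet(synth_titration(K = 200, sigma_r = 0))
  s12 <- select_quiet(synth_titration(K = 5e4, stoichiometry = "1:2",
                                      sigma_r = 0))
  expect_identical(s11$selected, "1:1")
  expect_identical(s12$selected, "1:2")
  expect_lt(s11$delta_aicc, -10)
  expect_gt(s12$delta_aicc, 10)
})

test_that("titration container enforces its invariants", {
  expect_error(titration(c(0, 2e-3, 1e-3), c(0.01, 0.02, 0.03),
                         298, "PBS_pH7.4", 1e-6), "increasing")
  expect_error(titration(c(1e-3, 2e-3), c(0.01, 0.02), 298, "PBS_pH7.4",
                         1e-6), "zero-host")
  expect_error(titration(c(0, 1e-3), c(0.01, 0.9), 298, "PBS_pH7.4",
                         1e-6), "physical range")
  expect_error(titration(c(0, 1e-3), c(0.01, 0.02), 298, "PBS_pH7.4",
                         -1), "positive")
})
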