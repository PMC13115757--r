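test_that("generators are byte-deterministic under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- list(scenario = "mtt", seed = 9,
              parameters = list(sigma = 5))
  generate(cfg, d1)
  generate(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every scenario emits files that pass input validation", {
  td <- tempfile(); dir.create(td)
  scenarios <- c("cmbcd_1to1", "ambcd_1to2", "solubility", "decay",
                 "quench", "release", "mtt")
  files <- character()
  for (sc in scenarios) {
    out <- generate(list(scenario = sc, seed = 3), td)
    files <- c(files, out$files)
    expect_true(file.exists(out$truth_file))
  }
  v <- validate_inputs(files)
  expect_true(all(v$status == "ok"))
  unlink(td, recursive = TRUE)
})

test_that("ground-truth sidecars carry the generating parameters", {
  td <- tempfile(); dir.create(td)
  out <- generate(list(scenario = "release", seed = 4,
                       parameters = list(k = 0.02)), td)
  truth <- jsonlite::read_json(out$truth_file, simplifyVector = TRUE)
  expect_equal(truth$k, 0.02)
  expect_equal(truth$tau_half, log(2) / 0.02, tolerance = 1e-9)
  expect_identical(truth$scenario, "release")
  unlink(td, recursive = TRUE)
})

test_that("noise-zero scenarios round-trip through their consumers", {
  # titration -> isotherm fit
  tit <- synth_titration(K = 200, sigma_r = 0)
  expect_lt(abs(fit_binding_isotherm(tit, "1:1")$K - 200) / 200, 1e-3)
  # 1:2 defaults are selected as 1:2
  t12 <- synth_titration(K = 5e4, stoichiometry = "1:2", sigma_r = 0)
  expect_identical(select_quiet(t12)$selected, "1:2")
  # quench -> Stern-Volmer
  sv <- stern_volmer_fit(synth_quench(K_SV = 120))
  expect_equal(sv$K_SV, attr(synth_quench(K_SV = 120), "truth")$K_SV,
               tolerance = 1e-9)
  # mtt -> IC50
  expect_equal(fit_ic50(synth_mtt(sigma = 0))$ic50, 17e-9,
               tolerance = 1e-6)
})

test_that("unknown scenarios are rejected", {
  expect_error(generate(list(scenario = "nmr", seed = 1), tempdir()),
               "unknown scenario")
})
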