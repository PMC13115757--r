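# Independent bisection oracle for the 1:1 mass-balance equilibrium,
# root-found directly on the bound-fraction scale f in [0, min(1, H/G)]:
# K (1 - f)(H - f G) = f. Independent of the closed-form quadratic
# solver, and precise on the scale the comparison is made on.
fraction_oracle_1to1 <- function(K, G, H, tol = 1e-13) {
  if (K == 0 || H == 0) return(0)
  g <- function(f) K * (1 - f) * (H - f * G) - f
  upper <- min(1, H / G)
  stats::uniroot(g, c(0, upper), tol = tol)$root
}

# quiet wrappers used where fit warnings are part of the exercise
fit_quiet <- function(...) suppressWarnings(fit_binding_isotherm(...))
select_quiet <- function(...) suppressWarnings(select_stoichiometry(...))
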