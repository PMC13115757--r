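#' Bound guest fraction for a 1:1 host-guest equilibrium
#'
#' Mass-action equilibrium \eqn{G + H \rightleftharpoons GH} with
#' association constant \eqn{K} (dm3 mol-1). In `"exact"` mode the complex
#' concentration \eqn{c} solves the mass-balance quadratic
#' \deqn{K c^2 - (K G_t + K H_t + 1) c + K G_t H_t = 0,}
#' and the bound fraction is \eqn{c/G_t}. In `"host_excess"` mode the host
#' is assumed undepleted (the usual titration regime, host in mM while the
#' guest is in uM) and the fraction reduces to
#' \eqn{K H_t / (1 + K H_t)}.
#'
#' The physical root of the quadratic (the one with
#' \eqn{c \le \min(G_t, H_t)}) is evaluated in the numerically stable
#' product form \eqn{c = 2 K G_t H_t / (b + \sqrt{b^2 - 4 K^2 G_t H_t})}
#' with \eqn{b = K G_t + K H_t + 1}, which avoids catastrophic
#' cancellation at small \eqn{K G_t H_t}.
#'
#' @param K Association constant, dm3 mol-1, >= 0.
#' @param guest_total Total guest concentration, mol dm-3 (exact mode).
#' @param host_total Total host concentration, mol dm-3. Vectorised.
#' @param mode `"exact"` or `"host_excess"`.
#' @return Bound guest fraction in `[0, 1]`, same length as `host_total`.
#' @export
#' @examples
#' complex_fraction_1to1(200, host_total = 5e-3, mode = "host_excess")  # 0.5
#' complex_fraction_1to1(200, guest_total = 1e-6, host_total = 5e-3)
complex_fraction_1to1 <- function(K, guest_total = NULL, host_total,
                                  mode = c("exact", "host_excess")) {
  mode <- match.arg(mode)
  .check_nonneg(K, "K")
  .check_numeric_vec(host_total, "host_total")
  if (any(host_total < 0)) .stop_domain("`host_total` must be non-negative")
  if (mode == "host_excess") {
    return(K * host_total / (1 + K * host_total))
  }
  .check_positive(guest_total, "guest_total")
  if (K == 0) return(rep(0, length(host_total)))
  G <- guest_total
  H <- host_total
  b <- K * G + K * H + 1
  disc <- b^2 - 4 * K^2 * G * H
  if (any(disc < 0))
    stop("mass-balance quadratic has no real root (numerical error); ",
         "inputs: K=", K, ", G=", G, call. = FALSE)
  cc <- 2 * K * G * H / (b + sqrt(disc))
  f <- cc / G
  pmin(pmax(f, 0), 1)
}

#' Bound guest fraction for a 1:2 (guest:host) equilibrium
#'
#' Overall two-step complexation \eqn{G + 2H \rightleftharpoons GH_2}
#' described by a single overall constant \eqn{K} (dm6 mol-2), with the
#' host assumed in large excess over the guest. The bound fraction is
#' \deqn{f = K H^2 / (1 + K H^2),}
#' which is sigmoidal in \eqn{H} on a logarithmic axis with
#' half-saturation at \eqn{H = K^{-1/2}}. No explicit 1:1 intermediate is
#' modelled.
#'
#' @param K_overall Overall association constant, dm6 mol-2, >= 0.
#' @param host_total Total host concentration, mol dm-3. Vectorised.
#' @return Bound guest fraction in `[0, 1)`.
#' @export
#' @examples
#' complex_fraction_1to2(1e8, 1e-3)       # 100/101
#' complex_fraction_1to2(1e8, 1e-4)       # half-saturation
complex_fraction_1to2 <- function(K_overall, host_total) {
  .check_nonneg(K_overall, "K_overall")
  .check_numeric_vec(host_total, "host_total")
  if (any(host_total < 0)) .stop_domain("`host_total` must be non-negative")
  x <- K_overall * host_total^2
  x / (1 + x)
}
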