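#' Van't Hoff analysis of temperature-dependent association constants
#'
#' Ordinary least-squares regression of \eqn{\ln K} on \eqn{1/T}:
#' \deqn{\ln K = -\frac{\Delta H}{R}\frac{1}{T} + \frac{\Delta S}{R},}
#' so \eqn{\Delta H = -R \cdot \mathrm{slope}} and
#' \eqn{\Delta S = R \cdot \mathrm{intercept}}, with
#' \eqn{R = 8.314} J K-1 mol-1. This assumes a temperature-independent
#' enthalpy (\eqn{\Delta C_p = 0}) over the studied range. Unweighted by
#' default; per-temperature weights may be supplied.
#'
#' @param temperature Temperatures in kelvin (>= 2 distinct values).
#'   Duplicated temperatures are collapsed by averaging \eqn{\ln K} with a
#'   warning.
#' @param K Association constants at each temperature, all > 0.
#' @param weights Optional regression weights (same length as the
#'   collapsed temperature vector).
#' @return An object of class `"vant_hoff"`: list with `dH` (kJ mol-1),
#'   `dS` (J K-1 mol-1), `std_errors` (same units), `n_temperatures`,
#'   `r_squared` and the underlying `lm` fit. Supports `print()`,
#'   `coef()`, `predict()` and [dG_at()].
#' @export
#' @examples
#' Tk <- seq(278.15, 318.15, by = 10)
#' K <- vant_hoff_K(Tk, dH = -26.2, dS = -56.1)  # PBS-like parameters
#' vant_hoff_fit(Tk, K)
vant_hoff_fit <- function(temperature, K, weights = NULL) {
  .check_numeric_vec(temperature, "temperature", 2L)
  .check_numeric_vec(K, "K", 2L)
  if (length(temperature) != length(K))
    .stop_domain("`temperature` and `K` must have equal length")
  if (any(temperature <= 0)) .stop_domain("`temperature` must be positive (K)")
  if (any(K <= 0)) .stop_domain("all `K` must be positive")
  if (anyDuplicated(temperature)) {
    warning("duplicate temperatures collapsed by averaging ln K",
            call. = FALSE)
    lk <- tapply(log(K), temperature, mean)
    temperature <- as.numeric(names(lk))
    lnK <- as.numeric(lk)
  } else lnK <- log(K)
  if (length(unique(temperature)) < 2)
    .stop_domain("at least 2 distinct temperatures are required")
  invT <- 1 / temperature
  fit <- if (is.null(weights)) lm(lnK ~ invT)
         else lm(lnK ~ invT, weights = weights)
  b <- coef(fit)
  se <- if (length(temperature) > 2) suppressWarnings(sqrt(diag(vcov(fit))))
        else c(`(Intercept)` = 0, invT = 0)  # two points: exact interpolation
  out <- list(
    dH = unname(-b[["invT"]] * .R_GAS) / 1000,        # kJ/mol
    dS = unname(b[["(Intercept)"]] * .R_GAS),         # J/K/mol
    std_errors = c(dH = unname(se[["invT"]]) * .R_GAS / 1000,
                   dS = unname(se[["(Intercept)"]]) * .R_GAS),
    n_temperatures = length(temperature),
    r_squared = if (length(temperature) > 2) .r_squared(fit) else 1,
    lm = fit, temperature = temperature, K = exp(lnK))
  class(out) <- "vant_hoff"
  out
}

#' Gibbs energy of complexation at a temperature
#'
#' \eqn{\Delta G(T) = \Delta H - T \Delta S / 1000} in kJ mol-1
#' (\eqn{\Delta H} in kJ mol-1, \eqn{\Delta S} in J K-1 mol-1).
#'
#' @param thermo A `"vant_hoff"` fit.
#' @param T Temperature(s), kelvin.
#' @return Gibbs energy, kJ mol-1.
#' @export
dG_at <- function(thermo, T = 298.15) {
  stopifnot(inherits(thermo, "vant_hoff"))
  if (any(T <= 0)) .stop_domain("`T` must be positive")
  thermo$dH - T * thermo$dS / 1000
}

#' Predict an association constant from thermodynamic parameters
#'
#' Inverts the van't Hoff relation:
#' \eqn{K(T) = \exp(-\Delta G(T) / (R T))} with \eqn{\Delta G} in J mol-1.
#'
#' @inheritParams dG_at
#' @return Predicted association constant(s).
#' @export
predict_K <- function(thermo, T = 298.15) {
  exp(-dG_at(thermo, T) * 1000 / (.R_GAS * T))
}

#' Association constants on a van't Hoff grid
#'
#' Convenience inverse used by the synthetic generators: exact
#' \eqn{K(T)} from \eqn{(\Delta H, \Delta S)}.
#'
#' @param temperature Temperatures, kelvin.
#' @param dH Enthalpy, kJ mol-1.
#' @param dS Entropy, J K-1 mol-1.
#' @return Association constants.
#' @export
vant_hoff_K <- function(temperature, dH, dS) {
  if (any(temperature <= 0)) .stop_domain("`temperature` must be positive")
  exp(-(dH * 1000 - temperature * dS) / (.R_GAS * temperature))
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("Van't Hoff analysis (ln K vs 1/T, ordinary least squares)\n")
  cat(sprintf("  dH = %.3g kJ/mol (se %.3g)\n", x$dH, x$std_errors[["dH"]]))
  cat(sprintf("  dS = %.3g J/K/mol (se %.3g)\n", x$dS, x$std_errors[["dS"]]))
  cat(sprintf("  dG(298.15 K) = %.3g kJ/mol, K(298.15 K) = %.4g\n",
              dG_at(x), predict_K(x)))
  cat(sprintf("  %d temperatures, R2 = %.5f\n", x$n_temperatures,
              x$r_squared))
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) c(dH = object$dH, dS = object$dS)

#' @export
predict.vant_hoff <- function(object, T = 298.15, ...) predict_K(object, T)
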