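#' Classify a Higuchi-Connors phase-solubility diagram
#'
#' Fits linear and quadratic models of total dissolved drug versus
#' cyclodextrin concentration and assigns the Higuchi-Connors type:
#' * `A_L` — linear increase (linear \eqn{R^2 \ge} `r2_linear`, positive
#'   slope), diagnostic of 1:1 complexation;
#' * `A_P` — positive curvature (quadratic coefficient significantly
#'   > 0 at `p_curv`), higher-order complexes;
#' * `A_N` — negative curvature (quadratic coefficient significantly
#'   < 0) while solubility still increases;
#' * `B` — plateau or decline at high cyclodextrin concentration
#'   (complex of limited solubility), detected when the upper tail stops
#'   rising or falls.
#'
#' @param diagram A [solubility_diagram()] with >= 4 points.
#' @param r2_linear Linearity threshold for the A_L call (default 0.98).
#' @param p_curv Significance level for the curvature test (default 0.05).
#' @return An object of class `"phase_solubility"`: list with `type`,
#'   `slope`, `intercept` (the operational intrinsic solubility
#'   \eqn{S_0}), `r_squared`, the stability constant `K` (dm3 mol-1, from
#'   [stability_constant()], `NA` unless type is `A_L` with slope < 1)
#'   and the underlying linear `lm`. Supports `print()` and `coef()`.
#' @export
classify_diagram <- function(diagram, r2_linear = 0.98, p_curv = 0.05) {
  stopifnot(inherits(diagram, "solubility_diagram"))
  if (nrow(diagram) < 4) .stop_domain("at least 4 points are required")
  x <- diagram$cd_conc
  y <- diagram$drug_total
  lin <- lm(y ~ x)
  slope <- unname(coef(lin)[2])
  intercept <- unname(coef(lin)[1])
  r2 <- .r_squared(lin)

  # curvature assessment on the quadratic term
  quad <- lm(y ~ x + I(x^2))
  qc <- suppressWarnings(summary(quad))$coefficients
  curv_coef <- if (nrow(qc) >= 3) qc[3, 1] else 0
  curv_p <- if (nrow(qc) >= 3 && !is.na(qc[3, 4])) qc[3, 4] else 1

  # B-type: upper third stops rising or declines
  n <- length(x)
  tail_idx <- which(x >= x[1] + 2 / 3 * (x[n] - x[1]))
  declining <- FALSE
  if (length(tail_idx) >= 2) {
    tail_fit <- lm(y[tail_idx] ~ x[tail_idx])
    tail_slope <- coef(tail_fit)[2]
    declining <- is.finite(tail_slope) &&
      tail_slope < 0.05 * max(slope, .Machine$double.eps) &&
      max(y[tail_idx]) >= max(y)  # plateau/decline occurs at the top
  }

  type <- if (declining && slope >= 0) "B"
    else if (r2 >= r2_linear && slope > 0) "A_L"
    else if (curv_p < p_curv && curv_coef > 0) "A_P"
    else if (curv_p < p_curv && curv_coef < 0) "A_N"
    else if (slope > 0) "A_L"   # weakly nonlinear but monotone rising
    else "B"

  S0 <- intercept
  K <- if (type == "A_L" && slope > 0 && slope < 1 && S0 > 0)
    stability_constant(slope, S0) else NA_real_
  out <- list(type = type, slope = slope, intercept = S0,
              r_squared = r2, K = K,
              curvature = curv_coef, curvature_p = curv_p,
              lm = lin, data = diagram)
  class(out) <- "phase_solubility"
  out
}

#' Stability constant from an A_L phase-solubility diagram
#'
#' For a 1:1 complex with an A_L (linear) diagram,
#' \deqn{K = \frac{\mathrm{slope}}{S_0 (1 - \mathrm{slope})}}
#' where \eqn{S_0} is the intrinsic solubility (the diagram intercept).
#' Valid only for 0 < slope < 1; a slope >= 1 is incompatible with the
#' 1:1 model.
#'
#' @param slope Diagram slope, dimensionless, in (0, 1).
#' @param S0 Intrinsic solubility, mol dm-3, > 0.
#' @return Stability constant, dm3 mol-1.
#' @export
#' @examples
#' stability_constant(0.5, 1e-4)  # 1e4 dm3/mol
stability_constant <- function(slope, S0) {
  .check_scalar(slope, "slope")
  .check_positive(S0, "S0")
  if (slope <= 0) .stop_domain("`slope` must be positive")
  if (slope >= 1)
    .stop_domain("`slope` >= 1: the 1:1 A_L formula is invalid")
  slope / (S0 * (1 - slope))
}

#' Solubility enhancement factor
#'
#' Fold increase in drug solubility in the presence of cyclodextrin,
#' optionally rounded to the nearest integer for report parity.
#'
#' @param S_with_cd Solubility with cyclodextrin, mol dm-3, > 0.
#' @param S_without Solubility without cyclodextrin, mol dm-3, > 0.
#' @param rounding `"none"` or `"nearest_int"`.
#' @return Fold factor.
#' @export
#' @examples
#' solubility_enhancement(4.6e-5, 7.7e-6, "nearest_int")  # 6
solubility_enhancement <- function(S_with_cd, S_without,
                                   rounding = c("none", "nearest_int")) {
  rounding <- match.arg(rounding)
  .check_positive(S_with_cd, "S_with_cd")
  .check_positive(S_without, "S_without")
  f <- S_with_cd / S_without
  if (rounding == "nearest_int") round(f) else f
}

#' @export
print.phase_solubility <- function(x, ...) {
  cat(sprintf("Phase-solubility diagram: type %s\n", x$type))
  cat(sprintf("  slope = %.4g, S0 (intercept) = %.4g mol/dm3, R2 = %.5f\n",
              x$slope, x$intercept, x$r_squared))
  if (is.finite(x$K))
    cat(sprintf("  stability constant K = %.4g dm3/mol\n", x$K))
  invisible(x)
}

#' @export
coef.phase_solubility <- function(object, ...) {
  c(slope = object$slope, S0 = object$intercept, K = object$K)
}

#' @export
plot.phase_solubility <- function(x, ...) {
  plot(x$data$cd_conc, x$data$drug_total, xlab = "[CD] (mol/dm3)",
       ylab = "total drug (mol/dm3)",
       main = sprintf("phase solubility (%s)", x$type), ...)
  abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}
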