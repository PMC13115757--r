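#' Percent cell survival from MTT absorbances
#'
#' \eqn{100 \cdot A_{treated} / A_{control}} with blank-subtracted
#' absorbances (blank subtraction happens upstream of this function).
#'
#' @param abs_treated Absorbance of the treated well(s), >= 0.
#' @param abs_control Absorbance of the untreated control, > 0.
#' @return Survival, percent. Vectorised over `abs_treated`.
#' @export
#' @examples
#' survival_percent(0.30, 0.60)  # 50%
survival_percent <- function(abs_treated, abs_control) {
  .check_numeric_vec(abs_treated, "abs_treated")
  .check_positive(abs_control, "abs_control")
  if (any(abs_treated < 0)) .stop_domain("`abs_treated` must be non-negative")
  100 * abs_treated / abs_control
}

# 4PL mean with top fixed; hill > 0, survival falls with dose
.fourpl <- function(dose, ic50, hill, bottom, top = 100) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

.fit_ic50_one <- function(dose, surv, top = 100) {
  mean_s <- surv
  if (min(mean_s) >= 50 || max(mean_s) <= 50)
    .stop_domain("mean survival does not cross 50%; IC50 would be an ",
                 "extrapolation")
  if (any(diff(mean_s[order(dose)]) > 15))
    message("non-monotone survival pattern in dose-response data")
  # start: dose nearest the 50% crossing by interpolation on log dose
  pos <- dose > 0
  ic0 <- tryCatch({
    o <- order(dose[pos])
    approx(mean_s[pos][o], log(dose[pos][o]), xout = 50, ties = mean)$y
  }, error = function(e) NA_real_)
  if (!is.finite(ic0)) ic0 <- log(stats::median(dose[pos]))
  dd <- data.frame(dose = dose, s = surv)
  ff <- tryCatch(
    minpack.lm::nlsLM(
      s ~ bottom + (top - bottom) / (1 + (dose / exp(lic50))^hill),
      data = dd,
      start = list(lic50 = ic0, hill = 1,
                   bottom = max(0, min(min(surv), top - 1))),
      lower = c(lic50 = -Inf, hill = 0.05, bottom = 0),
      upper = c(lic50 = Inf, hill = 20, bottom = top),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 500)),
    error = function(e) stop("IC50 fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- coef(ff)
  se <- tryCatch(summary(ff)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  list(ic50 = exp(cf[["lic50"]]),
       ic50_se = exp(cf[["lic50"]]) * se[["lic50"]],  # delta method
       hill = cf[["hill"]], bottom = cf[["bottom"]],
       rss = sum(residuals(ff)^2))
}

#' Fit a four-parameter logistic dose-response and estimate the IC50
#'
#' Fits \deqn{S(d) = bottom + \frac{top - bottom}{1 + (d/IC_{50})^{h}}}
#' with the top fixed at 100% (the untreated control defines 100% by
#' construction) and the bottom bounded at 0. With this parameterisation
#' \eqn{S(IC_{50}) = (top + bottom)/2}, so the IC50 is the dose at half
#' of the asymptote span. The dose-0 control row enters the fit (the
#' model evaluates to `top` at zero dose). The mean survival must cross
#' 50%; otherwise the IC50 would be an extrapolation and an error is
#' raised.
#'
#' By default the replicate means are fitted; `per_replicate = TRUE`
#' additionally fits each replicate column separately, yielding the
#' replicate-level IC50s used by [compare_ic50()].
#'
#' @param dr A [dose_response()].
#' @param per_replicate Also fit each replicate separately?
#' @return An object of class `"ic50_fit"`: list with `ic50` (mol dm-3),
#'   `ic50_se`, `hill`, `bottom`, `top`, and (if requested)
#'   `ic50_replicates`. Supports `print()`, `coef()`, `predict()` and
#'   `plot()`.
#' @export
fit_ic50 <- function(dr, per_replicate = FALSE) {
  stopifnot(inherits(dr, "dose_response"))
  if (length(unique(dr$dose)) < 5)
    .stop_domain("at least 5 dose levels are required")
  mean_s <- rowMeans(dr$survival)
  pooled <- .fit_ic50_one(dr$dose, mean_s)
  reps <- NULL
  if (per_replicate) {
    reps <- apply(dr$survival, 2, function(col)
      tryCatch(.fit_ic50_one(dr$dose, col)$ic50,
               error = function(e) NA_real_))
    reps <- unname(reps)
  }
  out <- list(ic50 = pooled$ic50, ic50_se = pooled$ic50_se,
              hill = pooled$hill, bottom = pooled$bottom, top = 100,
              ic50_replicates = reps, rss = pooled$rss, data = dr)
  class(out) <- "ic50_fit"
  out
}

#' Compare two groups of replicate IC50 estimates
#'
#' Two-sample, two-tailed Student's t-test (equal-variance form) on the
#' log-transformed IC50s — concentrations are compared on the log scale
#' because IC50 estimates are approximately log-normal. Significance is
#' declared at p < `alpha` (default 0.05).
#'
#' @param group_a,group_b Numeric vectors of replicate IC50s (>= 2 each,
#'   typically 3), or `"ic50_fit"` objects fitted with
#'   `per_replicate = TRUE`.
#' @param alpha Significance level.
#' @return An object of class `"ic50_comparison"`: list with
#'   `t_statistic`, `p_value`, `significant`, `df` and the group
#'   geometric means. Swapping the groups negates `t` and leaves `p`
#'   unchanged.
#' @export
#' @examples
#' compare_ic50(c(17e-9, 18e-9, 16e-9), c(50e-9, 55e-9, 48e-9))
compare_ic50 <- function(group_a, group_b, alpha = 0.05) {
  get_reps <- function(g, nm) {
    if (inherits(g, "ic50_fit")) {
      if (is.null(g$ic50_replicates))
        .stop_domain(sprintf("`%s` was fitted without per_replicate", nm))
      g <- g$ic50_replicates
    }
    g <- g[is.finite(g)]
    if (length(g) < 2)
      .stop_domain(sprintf("`%s` needs >= 2 finite replicates", nm))
    if (any(g <= 0)) .stop_domain(sprintf("`%s` must be positive", nm))
    g
  }
  a <- log(get_reps(group_a, "group_a"))
  b <- log(get_reps(group_b, "group_b"))
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- list(statistic = c(t = 0), p.value = 1,
                 parameter = c(df = length(a) + length(b) - 2))
    } else {
      tt <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                 p.value = 0,
                 parameter = c(df = length(a) + length(b) - 2))
    }
  } else {
    tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  }
  out <- list(t_statistic = unname(tt$statistic),
              p_value = tt$p.value,
              significant = tt$p.value < alpha,
              df = unname(tt$parameter),
              geomean_a = exp(mean(a)), geomean_b = exp(mean(b)),
              alpha = alpha)
  class(out) <- "ic50_comparison"
  out
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("4PL dose-response fit (%s / %s)\n", x$data$cell_line,
              x$data$treatment))
  cat(sprintf("  IC50 = %.4g mol/dm3 (se %.3g) = %.3g nM\n",
              x$ic50, x$ic50_se, x$ic50 * 1e9))
  cat(sprintf("  Hill = %.3g, bottom = %.3g%%, top fixed at 100%%\n",
              x$hill, x$bottom))
  if (!is.null(x$ic50_replicates))
    cat("  replicate IC50s (nM):",
        paste(signif(x$ic50_replicates * 1e9, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, bottom = object$bottom,
    top = object$top)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose
       else if (is.data.frame(newdata)) newdata$dose else newdata
  .fourpl(d, object$ic50, object$hill, object$bottom, object$top)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data$dose
  pos <- d > 0
  plot(rep(d[pos], ncol(x$data$survival)), x$data$survival[pos, ],
       log = "x", xlab = "dose (mol/dm3)", ylab = "survival (%)",
       main = sprintf("IC50 = %.3g nM", x$ic50 * 1e9), ...)
  dd <- exp(seq(log(min(d[pos])), log(max(d)), length.out = 200))
  lines(dd, predict(x, dd), col = "steelblue")
  abline(h = (100 + x$bottom) / 2, lty = 3)
  invisible(x)
}

#' @export
print.ic50_comparison <- function(x, ...) {
  cat("Two-tailed Student's t-test on log IC50\n")
  cat(sprintf("  t = %.4g (df %.3g), p = %.4g -> %s at alpha = %g\n",
              x$t_statistic, x$df, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  cat(sprintf("  geometric means: %.3g vs %.3g mol/dm3\n",
              x$geomean_a, x$geomean_b))
  invisible(x)
}
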