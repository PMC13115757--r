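# Internal argument checking. All user-facing errors are raised with
# call. = FALSE so the message names the offending quantity, not the
# internal call stack.

.stop_domain <- function(...) stop(..., call. = FALSE)

.check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stop_domain(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

.check_nonneg <- function(x, name) {
  .check_scalar(x, name)
  if (x < 0) .stop_domain(sprintf("`%s` must be non-negative (got %g)", name, x))
  invisible(x)
}

.check_positive <- function(x, name) {
  .check_scalar(x, name)
  if (x <= 0) .stop_domain(sprintf("`%s` must be positive (got %g)", name, x))
  invisible(x)
}

.check_numeric_vec <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x) || any(!is.finite(x)))
    .stop_domain(sprintf("`%s` must be a finite numeric vector of length >= %d",
                         name, min_len))
  invisible(x)
}

# R-squared of a simple linear model
.r_squared <- function(fit) {
  y <- fitted(fit) + residuals(fit)
  1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
}

# Small-sample-corrected Akaike information criterion from a residual sum
# of squares (Gaussian likelihood, k counts the variance parameter).
.aicc_from_rss <- function(rss, n, k) {
  rss <- max(rss, .Machine$double.xmin)
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}
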