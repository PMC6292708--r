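#' One-tailed OLS slope test of h2c on chromosome size
#'
#' Fits a simple linear regression (with intercept) of `h2c` on the table's
#' size proxy and tests the null hypothesis that the slope is non-positive
#' (beta <= 0) against beta > 0, the standard chromosome partitioning test.
#' The one-tailed P value is the upper-tail t probability with n - 2
#' residual degrees of freedom.
#'
#' Degenerate cases follow fixed conventions: a perfect fit (zero residual
#' variance, nonzero slope) returns P = 0 for a positive slope and P = 1
#' for a negative one; a constant response returns t = 0 and one-tailed
#' P = 0.5.
#'
#' @param table a [partition_table].
#' @param tail `"greater"` (one-tailed, the default and the convention of
#'   the partitioning literature) or `"two-sided"`; selects which P value
#'   is reported as `p`, both are always computed.
#' @return An object of class `"partition_lm"`: a list with `beta`,
#'   `se_beta`, `t_stat`, `df`, `p_one_tailed`, `p_two_tailed`, `p`,
#'   `r2_adj`, `weighted`, and the underlying `lm` fit (`fit`).
#' @examples
#' pt <- partition_table(chrom = paste0("c", 1:6),
#'                       n_snp = c(100, 200, 300, 400, 500, 600),
#'                       h2c   = c(0.011, 0.018, 0.030, 0.041, 0.039, 0.062),
#'                       se    = sqrt(c(100, 200, 300, 400, 500, 600)) / 1e4)
#' ols_slope_test(pt)
#' @seealso [wls_slope_test()], [hc_correct()]
#' @export
ols_slope_test <- function(table, tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  table <- validate_partition_table(table)
  x <- .size_values(table)
  .slope_test(x, table$h2c, w = NULL, tail = tail)
}

#' Weighted least squares slope test with weights 1/SE^2
#'
#' As [ols_slope_test()] but each chromosome is weighted by the inverse
#' squared standard error of its h2c estimate, the textbook remedy for
#' heteroscedasticity (it does not address censoring, which is why WLS
#' alone does not remove the inflation).
#'
#' @inheritParams ols_slope_test
#' @return An object of class `"partition_lm"` with `weighted = TRUE`.
#' @export
wls_slope_test <- function(table, tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  table <- validate_partition_table(table)
  x <- .size_values(table)
  .slope_test(x, table$h2c, w = 1 / table$se^2, tail = tail)
}

.slope_test <- function(x, y, w = NULL, tail = "greater") {
  n <- length(x)
  if (n < 3) stop("validation error: need >= 3 points", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate design: all size values identical", call. = FALSE)
  }
  dat <- data.frame(x = x, y = y)
  fit <- if (is.null(w)) lm(y ~ x, data = dat) else lm(y ~ x, data = dat, weights = w)
  beta <- unname(coef(fit)[2])
  df <- n - 2L
  sm <- suppressWarnings(summary(fit))
  se_beta <- sm$coefficients["x", "Std. Error"]
  rss <- sum((if (is.null(w)) 1 else w) * resid(fit)^2)
  if (!is.finite(se_beta) || rss <= .Machine$double.eps * sum(y^2 + 1)) {
    # zero residual variance: conventions for perfect fit / constant response
    if (abs(beta) <= .Machine$double.eps * max(abs(y), 1)) {
      t_stat <- 0; p1 <- 0.5; p2 <- 1
    } else if (beta > 0) {
      t_stat <- Inf; p1 <- 0; p2 <- 0
    } else {
      t_stat <- -Inf; p1 <- 1; p2 <- 0
    }
    se_beta <- 0
  } else {
    t_stat <- beta / se_beta
    p1 <- pt(t_stat, df, lower.tail = FALSE)
    p2 <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  }
  out <- list(beta = beta, se_beta = se_beta, t_stat = t_stat, df = df,
              p_one_tailed = p1, p_two_tailed = p2,
              p = if (tail == "greater") p1 else p2,
              tail = tail,
              r2_adj = sm$adj.r.squared,
              weighted = !is.null(w), fit = fit)
  class(out) <- "partition_lm"
  out
}

# Fast closed-form one-tailed OLS P value, used inside resampling loops.
# Same conventions as .slope_test; no lm() overhead.
.ols_p_one <- function(x, y, sxx = NULL, mx = NULL) {
  n <- length(x)
  if (is.null(mx)) mx <- mean(x)
  if (is.null(sxx)) sxx <- sum((x - mx)^2)
  my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sxx
  res <- y - my - b * (x - mx)
  s2 <- sum(res^2) / (n - 2)
  if (s2 <= .Machine$double.eps^2 * max(my^2, 1)) {
    if (abs(b) <= .Machine$double.eps * max(abs(y), 1)) return(0.5)
    return(if (b > 0) 0 else 1)
  }
  pt(b / sqrt(s2 / sxx), n - 2, lower.tail = FALSE)
}

#' @export
print.partition_lm <- function(x, ...) {
  cat(sprintf("%s slope test of h2c on chromosome size\n",
              if (x$weighted) "WLS (weights 1/SE^2)" else "OLS"))
  cat(sprintf("  beta = %.4g (SE %.4g), t = %.4g on %d df\n",
              x$beta, x$se_beta, x$t_stat, x$df))
  cat(sprintf("  one-tailed P (H0: beta <= 0) = %.4g, two-tailed P = %.4g\n",
              x$p_one_tailed, x$p_two_tailed))
  cat(sprintf("  adjusted R^2 = %.3f\n", x$r2_adj))
  invisible(x)
}

#' @export
coef.partition_lm <- function(object, ...) coef(object$fit)

#' @export
residuals.partition_lm <- function(object, ...) resid(object$fit)

#' @export
predict.partition_lm <- function(object, ...) predict(object$fit, ...)

#' @export
as.data.frame.partition_lm <- function(x, ...) {
  data.frame(beta = x$beta, se_beta = x$se_beta, t = x$t_stat, df = x$df,
             p_one_tailed = x$p_one_tailed, p_two_tailed = x$p_two_tailed,
             r2_adj = x$r2_adj, weighted = x$weighted)
}

#' QQ-plot inflation factor of a set of P values
#'
#' Under a true null, P values are uniform on (0, 1). Deviation is measured
#' as the slope of observed versus expected -log10 P in a quantile-quantile
#' plot: the observed P values are sorted ascending, the expected quantile
#' of rank i among n is (i - 0.5)/n, and the slope of observed on expected
#' -log10 P is fitted through the origin (lambda = 1 for a calibrated test).
#' A free-intercept variant is available for sensitivity analysis; the
#' fixed-origin fit is the canonical estimate.
#'
#' @param pvalues numeric vector of at least 20 P values in (0, 1].
#' @param intercept if `TRUE`, fit with a free intercept instead of through
#'   the origin.
#' @return Object of class `"inflation_estimate"`: list with `lam`,
#'   `n_tests`, `intercept`.
#' @examples
#' n <- 1000
#' qq_lambda((seq_len(n) - 0.5) / n)$lam        # exactly 1
#' qq_lambda(((seq_len(n) - 0.5) / n)^2)$lam    # exactly 2
#' @export
qq_lambda <- function(pvalues, intercept = FALSE) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) < 20) {
    stop("validation error: need >= 20 P values for a stable slope, got ",
         length(pvalues), call. = FALSE)
  }
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("validation error: P values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(pvalues)
  o <- -log10(sort(pvalues))
  e <- -log10((seq_len(n) - 0.5) / n)
  lam <- if (intercept) {
    unname(coef(lm(o ~ e))[2])
  } else {
    sum(o * e) / sum(e^2)
  }
  out <- list(lam = lam, n_tests = n, intercept = intercept)
  class(out) <- "inflation_estimate"
  out
}

#' @export
print.inflation_estimate <- function(x, ...) {
  cat(sprintf("P value inflation lambda = %.3f (%d tests, %s fit)\n",
              x$lam, x$n_tests,
              if (x$intercept) "free-intercept" else "through-origin"))
  invisible(x)
}

#' Per-test inflation ratio lambda_cor
#'
#' The ratio of an HC-corrected P value to its uncorrected counterpart, a
#' point estimate of P value inflation for a single test (the QQ-slope
#' lambda, in contrast, needs many tests; the two are defined on different
#' scales and are not numerically interchangeable).
#'
#' @param p_hc HC-corrected P value in (0, 1].
#' @param p_unc uncorrected P value in (0, 1].
#' @return The ratio `p_hc / p_unc`.
#' @examples
#' lambda_cor(0.10, 0.02)  # 5
#' @export
lambda_cor <- function(p_hc, p_unc) {
  for (p in list(p_hc, p_unc)) {
    if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p > 1) {
      stop("validation error: P values must be single numbers in (0, 1]",
           call. = FALSE)
    }
  }
  p_hc / p_unc
}
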