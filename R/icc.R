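#' Intraclass correlation for absolute agreement (two-way random effects)
#'
#' Computes the ICC under the two-way random-effects ANOVA model
#' `y_ij = mu + r_i + c_j + e_ij` (rows = subjects, columns = measurement
#' sources), for absolute agreement. With `n` subjects, `k` columns and
#' mean squares `MSR` (rows), `MSC` (columns), `MSE` (error):
#' \deqn{ICC(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' for average measures, and
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + k(MSC - MSE)/n}}
#' for single measures. The 95% confidence interval uses the F-based
#' procedure of McGraw & Wong (single-measures bounds with a
#' Satterthwaite-approximated denominator df, stepped up to average
#' measures via the Spearman-Brown relation).
#'
#' Negative point estimates are reported as computed (not truncated); the
#' qualitative band maps them to "poor". Matrices with zero total variance
#' are rejected as degenerate; a matrix whose columns agree perfectly
#' (zero residual and zero column variance) returns ICC 1 with a
#' degenerate `[1, 1]` interval.
#'
#' @param x numeric matrix (or data.frame), subjects in rows, measurement
#'   sources in columns; no missing cells, `n >= 2`, `k >= 2`.
#' @param alpha two-sided error rate for the confidence interval.
#' @param measures `"average"` (default, ICC(A,k)) or `"single"`
#'   (ICC(A,1)).
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `n`, `k`, the ANOVA mean squares (`ms_rows`, `ms_cols`,
#'   `ms_err`), the qualitative `band`, `measures` and `alpha`.
#' @references McGraw, K. O., & Wong, S. P. (1996). Forming inferences
#'   about some intraclass correlation coefficients. Psychological
#'   Methods, 1(1), 30-46.
#' @export
#' @examples
#' m <- cbind(period = c(70, 75, 82, 90), reference = c(72, 74, 85, 88))
#' icc_a_k(m)
icc_a_k <- function(x, alpha = 0.05, measures = c("average", "single")) {
  measures <- match.arg(measures)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("matrix must be numeric", call. = FALSE)
  if (anyNA(x)) stop("paired matrix must have no missing cells", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L) stop("insufficient data: need at least 2 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 measurement columns", call. = FALSE)

  grand <- mean(x)
  rmeans <- rowMeans(x)
  cmeans <- colMeans(x)
  ssr <- k * sum((rmeans - grand)^2)
  ssc <- n * sum((cmeans - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    stop("degenerate input: zero total variance", call. = FALSE)
  }

  mw <- mw_agreement(msr, msc, mse, n, k, alpha)
  if (measures == "average") {
    est <- mw$icck
    ci <- mw$cik
  } else {
    est <- mw$icc1
    ci <- mw$ci1
  }

  structure(
    list(icc = est, ci_low = ci[1], ci_high = ci[2], n = n, k = k,
         ms_rows = msr, ms_cols = msc, ms_err = mse,
         band = classify_band(est), measures = measures, alpha = alpha),
    class = "icc_result"
  )
}

# Point estimates and McGraw-Wong absolute-agreement interval from the
# two-way ANOVA mean squares.
mw_agreement <- function(msr, msc, mse, n, k, alpha = 0.05) {
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  if (mse == 0 && msc == 0) {
    ci1 <- c(1, 1)
  } else {
    # Satterthwaite df for the A,1 interval; finite limit k-1 as MSE -> 0
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    if (!is.finite(v)) v <- k - 1
    f_low <- qf(1 - alpha / 2, n - 1, v)
    f_up <- qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - f_low * mse) /
      (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f_up * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_up * msr)
    ci1 <- c(l1, u1)
  }
  list(icc1 = icc1, icck = icck, ci1 = ci1,
       cik = ci1 * k / (1 + (k - 1) * ci1))
}

#' Qualitative reliability band for an ICC point estimate
#'
#' ICC at or below 0.5 indicates poor reliability, above 0.5 up to 0.75
#' moderate, above 0.75 up to 0.9 good, and above 0.9 excellent. Negative
#' estimates fall in the poor band.
#'
#' @param icc finite numeric vector of ICC point estimates.
#' @return Character vector of bands.
#' @export
#' @examples
#' classify_band(c(0.5, 0.76, 0.91))
classify_band <- function(icc) {
  if (any(!is.finite(icc))) stop("icc must be finite", call. = FALSE)
  cut_pts <- c(-Inf, 0.5, 0.75, 0.9, Inf)
  as.character(cut(icc, breaks = cut_pts,
                   labels = c("poor", "moderate", "good", "excellent"),
                   right = TRUE))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%s) [%s measures], two-way random, absolute agreement\n",
              if (x$measures == "average") as.character(x$k) else "1",
              x$measures))
  cat(sprintf("  ICC = %.3f, %d%% CI [%.3f, %.3f]  (n = %d, k = %d) -> %s\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$n, x$k, x$band))
  invisible(x)
}
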