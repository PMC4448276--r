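# Categorical and summary statistics used to score collision cultures:
# proportion CI with continuity term, two-sample z and t tests, simple
# linear regression with R and p.

#' 95% confidence half-width for a scored proportion
#'
#' Cultures scored categorically (collision yes/no) give a proportion
#' `p = k/n`; its 95% confidence half-width is computed with a continuity
#' term as `1.96 * sqrt(p * (1 - p) / n) + 1 / (2 * n)`. The continuity term
#' keeps the interval non-degenerate at p = 0 or 1 (e.g. 0 of 10 cultures
#' gives a half-width of 5%, not 0).
#'
#' @param k Number of "yes" cultures (successes).
#' @param n Number of cultures scored (>= 1).
#' @return The half-width as a fraction in `[0, 1]`. Use
#'   [format_ci_percent()] to render it the way such results are reported.
#' @examples
#' proportion_ci_halfwidth(6, 9)    # ~0.364 -> "+/-36%"
#' proportion_ci_halfwidth(0, 10)   # 0.05   -> "+/-5%"
#' @export
proportion_ci_halfwidth <- function(k, n) {
  k <- as.numeric(k); n <- as.numeric(n)
  if (length(k) != 1L || length(n) != 1L || !is.finite(k) || !is.finite(n) ||
      n < 1 || k < 0 || k > n)
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  p <- k / n
  1.96 * sqrt(p * (1 - p) / n) + 1 / (2 * n)
}

#' @rdname proportion_ci_halfwidth
#' @param halfwidth A half-width fraction as returned by
#'   `proportion_ci_halfwidth()`.
#' @return `format_ci_percent()` returns a string such as `"±36%"`; values
#'   below 10% are shown with one decimal (`"±8.3%"` style).
#' @export
format_ci_percent <- function(halfwidth) {
  pct <- 100 * halfwidth
  ifelse(pct < 10, sprintf("±%.1f%%", pct),
         sprintf("±%.0f%%", pct))
}

#' Two-sample z test for proportions
#'
#' Pooled-proportion z statistic without continuity correction:
#' `z = (p1 - p2) / sqrt(pp (1 - pp) (1/n1 + 1/n2))` with
#' `pp = (k1 + k2) / (n1 + n2)`; the p-value comes from the normal tail(s).
#' Defaults to one-tailed (the direction of the observed difference), the
#' convention under which the package's worked examples match their expected
#' values; set `tails = 2` for a two-sided test.
#'
#' @param k1,n1 Successes and trials in the first group.
#' @param k2,n2 Successes and trials in the second group.
#' @param tails 1 or 2.
#' @return A list with `z`, `p`, `estimate` (the two proportions) and
#'   `tails`.
#' @examples
#' two_sample_z(6, 9, 0, 10)         # p ~ 0.0009
#' @export
two_sample_z <- function(k1, n1, k2, n2, tails = 1) {
  stopifnot(tails %in% c(1, 2))
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n with n >= 1 in both groups", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- tails * stats::pnorm(-abs(z))
  if (se == 0) p <- if (tails == 1) 0.5 else 1
  list(z = z, p = min(1, p), estimate = c(p1 = p1, p2 = p2), tails = tails)
}

#' Two-sample t test from summary statistics
#'
#' Student's t test computed from group means, standard deviations and
#' sample sizes (the form needed when only summaries are reported, e.g.
#' divergence-angle means with their sigma and n). The default pools the
#' variances with `df = n1 + n2 - 2`; `welch = TRUE` uses the
#' Welch-Satterthwaite unequal-variance form. Defaults to one-tailed in the
#' direction of the observed difference.
#'
#' @param mean1,sd1,n1 First group summary (n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @param tails 1 or 2.
#' @param welch Use the unequal-variance (Welch) form.
#' @return A list with `t`, `df`, `p` and `tails`.
#' @examples
#' two_sample_t_summary(133, 21.3, 33, 99.9, 24.3, 34)  # p ~ 5.7e-8
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 tails = 1, welch = FALSE) {
  stopifnot(tails %in% c(1, 2))
  if (n1 < 2 || n2 < 2 || sd1 < 0 || sd2 < 0 ||
      !all(is.finite(c(mean1, sd1, n1, mean2, sd2, n2))))
    stop("need finite summaries with n >= 2 and sd >= 0", call. = FALSE)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    return(list(t = 0, df = n1 + n2 - 2, p = 1, tails = tails))
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  p <- tails * stats::pt(-abs(t), df)
  list(t = t, df = df, p = min(1, p), tails = tails)
}

#' Simple linear regression with correlation and significance
#'
#' Least-squares fit of `y` on `x` in the spreadsheet-LINEST style: slope,
#' intercept, Pearson correlation R, and the two-tailed p-value of the
#' correlation from `t = R * sqrt((n - 2) / (1 - R^2))` with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @return An object of class `sa_regression`: list with `slope`,
#'   `intercept`, `r`, `t`, `df`, `p`, `n`.
#' @examples
#' fit <- linreg_r_p(1:5, c(2, 1, 4, 3, 5))
#' fit$slope; fit$r
#' @export
linreg_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x has zero variance", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  pv <- p_from_r(r, n)
  structure(list(slope = slope, intercept = intercept, r = r,
                 t = attr(pv, "t"), df = n - 2, p = as.numeric(pv), n = n),
            class = "sa_regression")
}

#' @rdname linreg_r_p
#' @param r A Pearson correlation coefficient.
#' @param n The number of observations it was computed from (`n >= 3`).
#' @return `p_from_r()` returns the two-tailed p-value of `r` (with the t
#'   statistic as attribute `"t"`); it also recovers the significance of a
#'   reported correlation, e.g. `p_from_r(0.67, 82)` is about `4.8e-12`.
#' @export
p_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) {
    t <- Inf
    p <- 0
  } else {
    t <- abs(r) * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-t, n - 2)
  }
  structure(p, t = t)
}

#' @export
print.sa_regression <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.6g + %.6g x  (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R = %.4f, t = %.4f on %d df, two-tailed p = %.3g\n",
              x$r, x$t, x$df, x$p))
  invisible(x)
}
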