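# Group comparison with a normality gate: Lilliefors-corrected
# Kolmogorov-Smirnov test on each group, Student's t when both pass,
# Mann-Whitney U otherwise; medians with interquartile ranges reported.

#' Normality test (Kolmogorov-Smirnov with Lilliefors correction)
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD, using Lilliefors-corrected p-values (appropriate when
#' the parameters are estimated from the sample). A constant sample is
#' non-normal by convention (p = 0).
#'
#' @param x numeric sample, n >= 5.
#' @return p-value.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need n >= 5 for the normality test", call. = FALSE)
  if (stats::sd(x) == 0) return(0)
  nortest::lillie.test(x)$p.value
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (full enumeration of rank
#' assignments) when the combined sample size is at most 16 and there are no
#' ties; otherwise the normal approximation with tie correction is used.
#'
#' @param x,y numeric samples, each n >= 3.
#' @return list with `U` (the Mann-Whitney statistic for `x`), `p`, and
#'   `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= 16
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Student's t-test (pooled variance)
#'
#' Classical two-sided two-sample t-test with pooled variance.
#'
#' @param x,y numeric samples, each n >= 3.
#' @return list with `t`, `p`, `df`, and `degenerate` (TRUE when the pooled
#'   variance is zero; then p = 1 for equal means and p = 0 otherwise).
#' @export
students_t <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                df = length(x) + length(y) - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Compare a metric between two groups
#'
#' The full group-comparison procedure: both groups are tested for normality
#' ([ks_normality()]); if both pass (p > alpha) the groups are compared with
#' a pooled-variance Student's t-test, otherwise with a Mann-Whitney U test.
#' Groups are summarized as median \[Q1, Q3\] (quartiles by linear
#' interpolation).
#'
#' @param x,y per-cell metric values for the two groups (each n >= 5).
#' @param labels group labels (length 2).
#' @param metric metric name for reporting.
#' @param alpha significance level (default 0.05).
#' @return object of class `"group_comparison"`.
#' @export
compare_groups <- function(x, y, labels = c("sham", "bbbd"),
                           metric = "metric", alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 5 || length(y) < 5)
    stop("each group needs n >= 5", call. = FALSE)
  p_norm <- c(ks_normality(x), ks_normality(y))
  use_t <- all(p_norm > alpha)
  res <- if (use_t) students_t(x, y) else mann_whitney(x, y)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qx <- qs(x); qy <- qs(y)
  out <- list(metric = metric, labels = labels, x = x, y = y,
              median = c(qx[2], qy[2]),
              q1 = c(qx[1], qy[1]), q3 = c(qx[3], qy[3]),
              iqr = c(qx[3] - qx[1], qy[3] - qy[1]),
              normality_p = p_norm,
              test = if (use_t) "t" else "MW",
              statistic = if (use_t) res$t else res$U,
              p_value = res$p,
              significant = res$p < alpha,
              alpha = alpha)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.4g [%.4g] vs. %s %.4g [%.4g], %s, p = %.4g%s\n",
              x$metric,
              x$labels[1], x$median[1], x$iqr[1],
              x$labels[2], x$median[2], x$iqr[2],
              if (x$test == "t") "t-test" else "MW",
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  print(object)
  cat(sprintf("  %s: n = %d, median %.4g [Q1 %.4g, Q3 %.4g], normality p = %.3g\n",
              object$labels[1], length(object$x), object$median[1],
              object$q1[1], object$q3[1], object$normality_p[1]))
  cat(sprintf("  %s: n = %d, median %.4g [Q1 %.4g, Q3 %.4g], normality p = %.3g\n",
              object$labels[2], length(object$y), object$median[2],
              object$q1[2], object$q3[2], object$normality_p[2]))
  cat(sprintf("  test: %s, statistic %.4g, alpha %.3g\n",
              if (object$test == "t") "Student's t (pooled)" else
                "Mann-Whitney U", object$statistic, object$alpha))
  invisible(object)
}

#' @export
plot.group_comparison <- function(x, ...) {
  graphics::boxplot(list(x$x, x$y), names = x$labels, ylab = x$metric, ...)
  graphics::stripchart(list(x$x, x$y), vertical = TRUE, add = TRUE,
                       pch = 16, col = "grey40", method = "jitter")
  invisible(x)
}
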