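# Group inference: pooled and paired t-tests that work from raw values or
# from printed summary statistics (mean, SD, n), TOST equivalence via the
# 90% confidence-interval inclusion rule, Bonferroni masking, and the
# n = 16 / Delta^2 sample-size rule.

#' Summary statistics of one group
#'
#' Container used by the summary-statistics paths of the t-test and
#' equivalence functions, so analyses can be reproduced from published
#' mean +/- SD tables without raw data.
#'
#' @param mean Group mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Number of observations (>= 2).
#' @return An object of class `summary_stats`.
#' @examples
#' summary_stats(13.01, 4.42, 5)
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)),
            class = "summary_stats")
}

as_summary <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (inherits(x, "group_summary"))
    return(summary_stats(x$mean, x$sd, x$n))
  x <- as.numeric(x)
  summary_stats(mean(x), stats::sd(x), length(x))
}

pooled_se <- function(a, b) {
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  list(se = sqrt(sp2 * (1 / a$n + 1 / b$n)), df = df, sp2 = sp2)
}

#' Two-sample t-test from raw values or summary statistics
#'
#' Equal-variance (pooled) test by default, the convention for these group
#' comparisons; Welch's unequal-variance form is available via
#' `var_equal = FALSE`. Raw vectors and `summary_stats` inputs give
#' identical results when the summaries are exact.
#'
#' @param a,b Numeric vectors, [summary_stats], or `group_summary` objects.
#' @param var_equal Pool the variances (default TRUE).
#' @return An object of class `nb_ttest`: list with `t`, `df`, `p`
#'   (two-tailed), `diff` (mean of a minus mean of b) and `se`.
#' @examples
#' ttest_two_sample(summary_stats(13.01, 4.42, 5), summary_stats(11.64, 1.80, 5))
#' @export
ttest_two_sample <- function(a, b, var_equal = TRUE) {
  a <- as_summary(a); b <- as_summary(b)
  if (var_equal) {
    ps <- pooled_se(a, b)
    if (ps$sp2 <= 0) stop("zero pooled variance", call. = FALSE)
    se <- ps$se; df <- ps$df
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    if (va + vb <= 0) stop("zero variance", call. = FALSE)
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  diff <- a$mean - b$mean
  tstat <- diff / se
  structure(list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
                 diff = diff, se = se, var_equal = var_equal),
            class = "nb_ttest")
}

#' Paired two-tailed t-test
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return An object of class `nb_ttest` (`diff` is the mean difference).
#' @export
ttest_paired <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of the paired differences", call. = FALSE)
  se <- sdd / sqrt(n)
  tstat <- mean(d) / se
  structure(list(t = tstat, df = n - 1,
                 p = 2 * stats::pt(-abs(tstat), n - 1),
                 diff = mean(d), se = se, var_equal = NA),
            class = "nb_ttest")
}

#' @export
print.nb_ttest <- function(x, ...) {
  cat(sprintf("<t-test> t = %.4f, df = %.4g, p = %.4f (diff %.3f +/- SE %.3f)\n",
              x$t, x$df, x$p, x$diff, x$se))
  invisible(x)
}

#' TOST equivalence test via the 90% confidence interval
#'
#' Two one-sided tests at level `alpha` (default 0.05) are equivalent to
#' checking whether the two-sided `1 - 2 alpha` (i.e. 90%) confidence
#' interval of the group difference lies strictly inside the equivalence
#' margins; that interval is also the quantity reported. The interval uses
#' the pooled (equal-variance) standard error.
#'
#' @param a,b Numeric vectors, [summary_stats], or `group_summary` objects.
#' @param margin_low,margin_high Equivalence margins (same units as the
#'   measure); `margin_low < margin_high`.
#' @param alpha Level of each one-sided test (default 0.05).
#' @return An object of class `tost_result` with `diff`, `ci90`
#'   (two-sided `1 - 2 alpha` CI), `equivalent`, the margins, and `df`.
#' @examples
#' tost_equivalence(summary_stats(13.01, 4.42, 5), summary_stats(11.64, 1.80, 5),
#'                  margin_low = -5.4, margin_high = 5.4)
#' @export
tost_equivalence <- function(a, b, margin_low, margin_high, alpha = 0.05) {
  if (!(margin_low < margin_high))
    stop("margin_low must be < margin_high", call. = FALSE)
  a <- as_summary(a); b <- as_summary(b)
  ps <- pooled_se(a, b)
  if (ps$sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  diff <- a$mean - b$mean
  tcrit <- stats::qt(1 - alpha, ps$df)
  ci <- c(diff - tcrit * ps$se, diff + tcrit * ps$se)
  structure(list(diff = diff, ci90 = ci,
                 equivalent = (ci[1L] > margin_low) && (ci[2L] < margin_high),
                 margin_low = margin_low, margin_high = margin_high,
                 alpha = alpha, df = ps$df, se = ps$se),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("<tost_result> diff %.2f, %d%% CI (%.2f, %.2f), margins (%.2f, %.2f): %s\n",
              x$diff, round(100 * (1 - 2 * x$alpha)), x$ci90[1L], x$ci90[2L],
              x$margin_low, x$margin_high,
              if (x$equivalent) "equivalent" else "not shown equivalent"))
  invisible(x)
}

#' Bonferroni significance mask
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise level (default 0.01).
#' @param m Number of tests; defaults to `length(p_values)` and must be at
#'   least that.
#' @return Logical vector: `p < alpha / m`.
#' @export
bonferroni_mask <- function(p_values, alpha = 0.01, m = length(p_values)) {
  if (m < length(p_values))
    stop("m must be at least the number of p-values considered", call. = FALSE)
  p_values < alpha / m
}

#' Sample-size rule n = 16 / Delta^2
#'
#' Standardizes the smallest relevant signal change `delta_signal` by the
#' baseline variation `sigma` (Delta = delta/sigma) and applies the
#' conventional rule of thumb n = 16 / Delta^2 for ~80% power at two-sided
#' alpha 0.05.
#'
#' @param delta_signal Relevant signal change (e.g. percent BOLD).
#' @param sigma Baseline standard deviation, same units (> 0).
#' @return An object of class `sample_size_spec` with `delta_signal`,
#'   `sigma`, `Delta`, real-valued `n` and `n_ceiling`.
#' @examples
#' sample_size_rule(0.5, 0.2)  # Delta 2.5, n = 2.56
#' @export
sample_size_rule <- function(delta_signal, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  Delta <- delta_signal / sigma
  n <- 16 / Delta^2
  structure(list(delta_signal = delta_signal, sigma = sigma,
                 Delta = Delta, n = n, n_ceiling = ceiling(n)),
            class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat(sprintf("<sample_size> Delta = %.3g, n = 16/Delta^2 = %.3g (ceiling %d)\n",
              x$Delta, x$n, x$n_ceiling))
  invisible(x)
}
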