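# Bootstrap confidence intervals and paired tests on per-comparison metric
# vectors: percentile bootstrap (1000 repetitions, alpha = 0.05 by
# default), Wilcoxon sign-rank, sign test, paired t-test.

#' Percentile bootstrap confidence interval
#'
#' Resamples `x` with replacement `n_boot` times and returns the
#' `alpha/2` and `1 - alpha/2` quantiles of the resampled statistic.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param x Numeric sample (n >= 2).
#' @param stat `"mean"` or `"median"`.
#' @param n_boot Number of bootstrap repetitions.
#' @param alpha Two-sided significance level.
#' @param seed Optional seed for the resampling stream.
#' @return An `estimate_ci`: list with `point`, `ci_lo`, `ci_hi`, `n`,
#'   `alpha`, `n_boot`.
#' @export
bootstrap_ci <- function(x, stat = c("mean", "median"), n_boot = 1000,
                         alpha = 0.05, seed = NULL) {
  stat <- match.arg(stat)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("undefined CI: need at least 2 observations")
  f <- if (stat == "mean") mean else stats::median
  draw <- function() {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    m <- matrix(x[idx], n, n_boot)
    if (stat == "mean") colMeans(m) else apply(m, 2, stats::median)
  }
  boots <- if (is.null(seed)) draw() else with_seed(seed, draw())
  q <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(point = f(x), ci_lo = q[1], ci_hi = q[2], n = n,
                 alpha = alpha, n_boot = n_boot),
            class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, ...) {
  cat(sprintf("%.4g [%.4g, %.4g] (n = %d, %d bootstrap reps, alpha = %g)\n",
              x$point, x$ci_lo, x$ci_hi, x$n, x$n_boot, x$alpha))
  invisible(x)
}

#' Wilcoxon sign-rank test against a zero median
#'
#' Two-sided p-value; zeros are dropped. The exact distribution is used for
#' n <= 25 without ties, the normal approximation with continuity
#' correction otherwise.
#'
#' @param x Numeric vector of paired differences.
#' @return Two-sided p-value, or `NA` if no nonzero entries remain.
#' @export
signrank_p <- function(x) {
  x <- x[is.finite(x) & x != 0]
  if (length(x) < 1) {
    warning("sign-rank test undefined: no nonzero entries")
    return(NA_real_)
  }
  exact <- length(x) <= 25 && !anyDuplicated(abs(x))
  stats::wilcox.test(x, mu = 0, exact = exact, correct = TRUE)$p.value
}

#' Exact sign test against a zero median
#'
#' Two-sided binomial test on the number of positive entries; zeros are
#' dropped.
#'
#' @param x Numeric vector of paired differences.
#' @return Two-sided p-value, or `NA` if no nonzero entries remain.
#' @export
signtest_p <- function(x) {
  x <- x[is.finite(x) & x != 0]
  if (length(x) < 1) {
    warning("sign test undefined: no nonzero entries")
    return(NA_real_)
  }
  stats::binom.test(sum(x > 0), length(x), p = 0.5)$p.value
}

#' Paired t-test against a zero mean
#'
#' @param x Numeric vector of paired differences (n >= 2).
#' @return Two-sided p-value.
#' @export
paired_t_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("t-test needs at least 2 observations")
  stats::t.test(x)$p.value
}
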