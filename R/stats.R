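#' Welch's two-sample t test
#'
#' Two-sided Welch's t (unequal variances, Welch-Satterthwaite degrees of
#' freedom). When both samples are constant, the test is degenerate: equal
#' constants return statistic 0 and p = 1, different constants an infinite
#' statistic and p = 0 (documented tie policy).
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return Object of class `sm_test`: list with `statistic`, `p_value`,
#'   `test`, `df`, `n` (per-group sizes).
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- mean(a) == mean(b)
    res <- list(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                p_value = if (eq) 1 else 0, df = NA_real_)
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(ht$statistic),
                p_value = ht$p.value, df = unname(ht$parameter))
  }
  structure(c(res, list(test = "Welch's t", n = c(length(a), length(b)))),
            class = "sm_test")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. Exact enumeration is used for small samples
#' (both n <= 8) without ties; larger samples or ties use the normal
#' approximation with tie correction and continuity correction. The
#' reported statistic is U for the first sample.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return `sm_test` with the U statistic.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 8L && length(b) <= 8L
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 df = NA_real_, test = "Mann-Whitney U",
                 n = c(length(a), length(b))),
            class = "sm_test")
}

#' @export
print.sm_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, two-sided p = %.4g (n = %s)%s\n",
              x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              paste0("  ", bonferroni_stars(x$p_value))))
  invisible(x)
}

#' Spearman's rank correlation
#'
#' @param x,y Paired numeric vectors (>= 3 pairs).
#' @return List of class `sm_correlation` with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(rho = unname(ht$estimate), p_value = ht$p.value,
                 n = length(x)),
            class = "sm_correlation")
}

#' @export
print.sm_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g)\n",
              x$rho, x$n, x$p_value))
  invisible(x)
}

#' Significance stars with optional Bonferroni adjustment
#'
#' Star labels under strict thresholds `0.05/m`, `0.01/m`, `0.001/m` for
#' `m` comparisons; `m = 1` gives the plain 0.05/0.01/0.001 convention and
#' `m = 3` the familiar 0.017/0.003/0.0003 Bonferroni-adjusted set (at
#' printed rounding).
#'
#' @param p Numeric vector of p values.
#' @param m Number of comparisons (>= 1).
#' @return Character vector: `""`, `"*"`, `"**"` or `"***"`. Monotone in p.
#' @export
bonferroni_stars <- function(p, m = 1L) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  vapply(p, function(pi) {
    if (pi < 0.001 / m) "***"
    else if (pi < 0.01 / m) "**"
    else if (pi < 0.05 / m) "*"
    else ""
  }, character(1L))
}

#' Box-and-whisker summary
#'
#' Five-number summary plus mean, with linear-interpolation (type 7)
#' quartiles and whiskers extending to the most extreme data points within
#' 1.5 x IQR beyond the box (the plotting convention used for temporal
#' fractions, frequencies and zone sizes).
#'
#' @param x Numeric vector (non-empty).
#' @return List of class `box_summary`: `n, min, max, mean, median, q1, q3,
#'   whisker_lo, whisker_hi`.
#' @export
box_summary <- function(x) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  structure(list(n = length(x), min = min(x), max = max(x), mean = mean(x),
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 whisker_lo = min(x[x >= q[1L] - 1.5 * iqr]),
                 whisker_hi = max(x[x <= q[3L] + 1.5 * iqr])),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(paste0("box summary (n = %d): median %.4g, mean %.4g\n",
                     " box [%.4g, %.4g], whiskers [%.4g, %.4g], ",
                     "range [%.4g, %.4g]\n"),
              x$n, x$median, x$mean, x$q1, x$q3,
              x$whisker_lo, x$whisker_hi, x$min, x$max))
  invisible(x)
}

#' Single-exponential lifetime fit
#'
#' Maximum-likelihood mean of exponentially distributed durations (the
#' sample mean), with an optional left-truncation correction: when only
#' durations exceeding a threshold `T` are observable, memorylessness gives
#' the underlying mean as `mean(durations) - T`.
#'
#' @param durations Positive durations, s (n >= 10).
#' @param truncation_s Left-truncation threshold `T`, s (default 0).
#' @return Fitted mean lifetime, s.
#' @export
fit_exponential_lifetime <- function(durations, truncation_s = 0) {
  stopifnot(length(durations) >= 10L, all(durations > 0),
            truncation_s >= 0, all(durations >= truncation_s))
  mean(durations) - truncation_s
}
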