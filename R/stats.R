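## Contingency-table and paired statistics used to evaluate grafting-
## strategy selections: continuity-corrected chi-squared, Fisher's exact
## test, exact McNemar, paired t, and the nonparametric fallbacks. These
## are standard tests (delegated to base R where possible); the module adds
## the explicit 2x2 interface and the expected-count-based test-selection
## policy.

#' 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer counts (rows = group, columns =
#'   outcome).
#' @return list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("empty table")
  structure(as.list(x), class = "contingency_2x2")
}

as_matrix_2x2 <- function(t) matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)

#' Continuity-corrected (Yates) chi-squared test on a 2x2 table
#'
#' `chi2 = n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at 0
#' when `|ad - bc| <= n/2`; p from the chi-squared(1) survival function.
#'
#' @param t a [contingency_2x2()].
#' @return list with `statistic` and `p` (two-sided).
#' @export
yates_chi2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("degenerate margin: chi-squared undefined (use fisher_exact)")
  num <- abs(a * d - b * c) - n / 2
  stat <- if (num <= 0) 0 else n * num^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of tables (with
#' the observed margins) no more probable than the observed one.
#'
#' @param t a [contingency_2x2()].
#' @return two-sided p-value.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  fisher.test(as_matrix_2x2(t))$p.value
}

#' Two-proportion comparison with the small-expected-count policy
#'
#' Uses [fisher_exact()] when any expected cell count is below 5 and
#' [yates_chi2()] otherwise.
#'
#' @param x1,n1 successes/trials in group 1.
#' @param x2,n2 successes/trials in group 2.
#' @return list with `test` (`"fisher"` or `"chi-squared"`), `p`, and
#'   `statistic` (NA for Fisher).
#' @export
compare_proportions <- function(x1, n1, x2, n2) {
  stopifnot(x1 <= n1, x2 <= n2, x1 >= 0, x2 >= 0)
  t <- contingency_2x2(x1, n1 - x1, x2, n2 - x2)
  m <- as_matrix_2x2(t)
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected < 5) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    list(test = "fisher", p = fisher_exact(t), statistic = NA_real_)
  } else {
    y <- yates_chi2(t)
    list(test = "chi-squared", p = y$p, statistic = y$statistic)
  }
}

#' Exact McNemar test on paired discordant counts
#'
#' `p = min(1, 2 * P(Binomial(b + c, 1/2) <= min(b, c)))`; `p = 1` when
#' there are no discordant pairs. Exact binomial form, well defined at zero
#' counts.
#'
#' @param b count of pairs changing 0 -> 1.
#' @param c count of pairs changing 1 -> 0.
#' @return two-sided p-value.
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("discordant counts must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Paired t-test
#'
#' @param x,y paired series of equal length (>= 2) with non-degenerate
#'   differences.
#' @return list with `t` and `p` (two-sided).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired series must have equal length >= 2")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero variance of differences: paired t undefined")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Nonparametric fallbacks
#'
#' Mann-Whitney U for independent samples, Wilcoxon signed-rank for paired
#' samples (thin wrappers, provided for completeness of the test-selection
#' policy).
#'
#' @param x,y samples.
#' @return two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) wilcox.test(x, y, exact = FALSE)$p.value

#' @rdname mann_whitney_u
#' @export
wilcoxon_signed_rank <- function(x, y)
  wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
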