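# Thin, contract-enforcing wrappers around the classical tests the
# pipeline relies on.  Raw-sample paths delegate to stats::t.test /
# stats::fisher.test; the summary-statistic Welch path is computed
# directly because published tables print means +/- SEM, not raw data.

test_result <- function(statistic, p_value, df = NA_real_) {
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 df = as.numeric(df)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, df = %.4g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Welch's unpaired two-sample t-test
#'
#' Two-tailed t-test without the equal-variance assumption, with
#' Welch-Satterthwaite degrees of freedom.  Raw samples are handed to
#' \code{stats::t.test}.
#'
#' @param x,y Numeric sample vectors (each of length >= 2 after removing
#'   missing values).
#' @return A \code{test_result} with \code{statistic}, \code{p_value} and
#'   fractional \code{df}.
#' @seealso [welch_t_summary()] for the means +/- SEM interface.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(test_result(0, 1, length(x) + length(y) - 2))
    stop("degenerate variance: both samples constant with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter))
}

#' Welch's t-test from summary statistics
#'
#' Published cohort tables report means +/- SEM per group; this path
#' reconstructs the Welch statistic directly from those summaries:
#' t = (m1 - m2) / sqrt(sem1^2 + sem2^2) with Welch-Satterthwaite df.
#'
#' @param mean1,mean2 Group means.
#' @param sem1,sem2 Standard errors of the means (must be > 0, or both 0
#'   with equal means).
#' @param n1,n2 Group sizes (>= 2).
#' @return A \code{test_result}.
#' @examples
#' # triglyceride baseline row of a matched cohort table:
#' welch_t_summary(97.6, 9.6, 20, 77.4, 12.0, 20)$p_value  # ~0.2
#' @export
welch_t_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sem1 < 0 || sem2 < 0) stop("SEMs must be non-negative")
  if (sem1 == 0 && sem2 == 0) {
    if (mean1 == mean2) return(test_result(0, 1, n1 + n2 - 2))
    stop("degenerate variance: zero SEM in both groups with unequal means")
  }
  v1 <- sem1^2; v2 <- sem2^2
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  test_result(tt, 2 * stats::pt(-abs(tt), df), df)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the hypergeometric null using the
#' minimum-likelihood rule (sum of all outcomes whose point probability
#' does not exceed that of the observed table), as implemented by
#' \code{stats::fisher.test}.
#'
#' @param table A \code{contingency_table} or count \code{a}.
#' @param b,c,d Remaining counts when given positionally.
#' @return A \code{test_result}; \code{statistic} is the conditional MLE
#'   odds ratio.
#' @export
fisher_exact <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!inherits(table, "contingency_table")) {
    table <- contingency_table(table, b, c, d)
  }
  if (table$a + table$b + table$c + table$d == 0) {
    stop("degenerate table: all cells are zero")
  }
  m <- matrix(base::c(table$a, table$b, table$c, table$d), nrow = 2,
              byrow = TRUE)
  ht <- stats::fisher.test(m)
  test_result(unname(ht$estimate), ht$p.value)
}

#' Paired t-test on pre/post measurements
#'
#' One-sample t-test on the within-patient differences (post - pre).
#' Pairs with a missing member are dropped.
#'
#' @param pre_values,post_values Equal-length numeric vectors.
#' @return A \code{test_result}.
#' @export
paired_t <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values)) {
    stop("pre and post vectors must have equal length")
  }
  keep <- !is.na(pre_values) & !is.na(post_values)
  d <- post_values[keep] - pre_values[keep]
  if (length(d) < 2) stop("fewer than 2 complete pairs")
  if (stats::var(d) == 0) {
    if (all(d == 0)) return(test_result(0, 1, length(d) - 1))
    stop("zero variance of differences")
  }
  ht <- stats::t.test(d)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values, order-aligned with the input, via
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
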