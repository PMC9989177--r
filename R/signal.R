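# Disproportionality statistics on 2x2 exposure-by-event tables.

#' Build a 2x2 exposure-by-event contingency table
#'
#' The atom of all disproportionality statistics: counts of spontaneous
#' reports cross-classified by exposure to a drug and occurrence of an
#' adverse event.
#'
#' @param a Reports with both the event and the exposure.
#' @param b Reports with the exposure but not the event.
#' @param c Reports with the event but not the exposure.
#' @param d Reports with neither.
#' @return An object of class \code{contingency_table} (a named list of the
#'   four counts).
#' @examples
#' contingency_table(2970, 65114, 60845, 11309102)
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- base::c(a = a, b = b, c = c, d = d)
  if (length(counts) != 4L || anyNA(counts)) {
    stop("all four cell counts must be supplied and non-missing")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  counts <- as.list(stats::setNames(as.numeric(counts), names(counts)))
  structure(counts, class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(base::c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Wald confidence interval and Z-score
#'
#' Computes the reporting odds ratio ROR = (a/b)/(c/d) on a 2x2 table of
#' exposure by event, its Wald confidence interval
#' exp(ln ROR +/- z* . SE) with SE = sqrt(1/a + 1/b + 1/c + 1/d), and the
#' Wald statistic Z = ln(ROR)/SE.  When any cell is zero the
#' Haldane-Anscombe continuity correction (0.5 added to all four cells) is
#' applied, keeping the ROR finite; this is standard pharmacovigilance
#' practice.
#'
#' @param table A \code{contingency_table}, or the count \code{a} when the
#'   four counts are given positionally.
#' @param b,c,d Remaining cell counts when \code{table} is the count
#'   \code{a}.
#' @param label Optional drug label carried into the result row.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A one-row \code{data.frame} with columns \code{label}, the four
#'   counts, \code{ror}, \code{ci_low}, \code{ci_high}, \code{z} and
#'   \code{n_exposed}.
#' @examples
#' ror_z(2970, 65114, 60845, 11309102)   # strong positive signal
#' ror_z(10, 90, 100, 900)               # equal proportions: ROR 1, Z 0
#' @export
ror_z <- function(table, b = NULL, c = NULL, d = NULL,
                  label = NA_character_, conf_level = 0.95) {
  if (!inherits(table, "contingency_table")) {
    table <- contingency_table(table, b, c, d)
  }
  a0 <- table$a; b0 <- table$b; c0 <- table$c; d0 <- table$d
  if (a0 + b0 + c0 + d0 == 0) stop("degenerate table: all cells are zero")
  if (a0 + b0 == 0) stop("empty exposed arm")
  if (c0 + d0 == 0) stop("empty unexposed arm")
  n_exposed <- a0 + b0
  if (min(a0, b0, c0, d0) == 0) {
    a0 <- a0 + 0.5; b0 <- b0 + 0.5; c0 <- c0 + 0.5; d0 <- d0 + 0.5
  }
  ror <- (a0 / b0) / (c0 / d0)
  se <- sqrt(1 / a0 + 1 / b0 + 1 / c0 + 1 / d0)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log(ror) / se
  data.frame(label = label,
             a = table$a, b = table$b, c = table$c, d = table$d,
             ror = ror,
             ci_low = exp(log(ror) - crit * se),
             ci_high = exp(log(ror) + crit * se),
             z = z,
             n_exposed = n_exposed,
             stringsAsFactors = FALSE)
}
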