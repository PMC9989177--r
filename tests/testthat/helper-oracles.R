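# Independent oracles used across the suite.  These deliberately avoid
# the package's own computational paths: direct formula evaluation,
# full enumeration, and exact arithmetic at tiny sizes.

# Fisher two-sided p by full hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood rule).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b          # exposed total
  n <- c + d          # unexposed total
  k <- a + c          # event total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(aa) {
    exp(lchoose(m, aa) + lchoose(n, k - aa) - lchoose(m + n, k))
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Audic-Claverie doubled-tail p for one conditioning by direct factorial
# evaluation (no log-space tricks); feasible for small x + y.  The upper
# tail continues from the point term via the exact term ratio
# p(y+1)/p(y) = t (x+y+1) / ((y+1)(1+t)) until terms vanish.
ac_direct_one <- function(x, y, t) {
  pf <- function(yy) {
    t^yy * factorial(x + yy) / (factorial(x) * factorial(yy) *
                                  (1 + t)^(x + yy + 1))
  }
  lower <- sum(vapply(0:y, pf, numeric(1)))
  term <- pf(y)
  upper <- term
  yy <- y
  while (term > upper * 1e-18 && yy < y + 1e6) {
    term <- term * t * (x + yy + 1) / ((yy + 1) * (1 + t))
    upper <- upper + term
    yy <- yy + 1
  }
  min(1, 2 * min(lower, upper))
}

ac_oracle <- function(x, y, n1, n2) {
  if (x + y == 0) return(1)  # no information
  min(ac_direct_one(x, y, n2 / n1), ac_direct_one(y, x, n1 / n2))
}

# Manual Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Small report table builder for fixture-style tests.
make_reports <- function(report_id, case_id, version, drugs, events) {
  data.frame(report_id = report_id, case_id = case_id,
             version = version, drugs = drugs, events = events,
             stringsAsFactors = FALSE)
}
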