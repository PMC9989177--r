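# Disproportionality screens over a deduplicated report corpus.

# Per-drug 2x2 counts against an event flag.  Returns a data.frame with
# drug, a (event & exposed) and n_exposed.
drug_event_counts <- function(drug_lists, event_flags) {
  lens <- lengths(drug_lists)
  long_drug <- unlist(drug_lists, use.names = FALSE)
  long_event <- rep(event_flags, lens)
  n_exposed <- table(long_drug)
  a <- tapply(long_event, long_drug, sum)
  data.frame(drug = names(n_exposed),
             a = as.numeric(a[names(n_exposed)]),
             n_exposed = as.numeric(n_exposed),
             stringsAsFactors = FALSE)
}

screen_rows <- function(counts, n_total, n_event, min_exposed) {
  counts <- counts[counts$n_exposed >= min_exposed, , drop = FALSE]
  if (nrow(counts) == 0) {
    return(data.frame(label = character(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), d = numeric(0), ror = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      z = numeric(0), n_exposed = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$a[i]
    b <- counts$n_exposed[i] - a
    cc <- n_event - a
    d <- n_total - counts$n_exposed[i] - cc
    ror_z(a, b, cc, d, label = counts$drug[i])
  })
  res <- do.call(rbind, rows)
  res <- res[order(-abs(res$z), res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' All-drugs disproportionality screen for an adverse event
#'
#' For every drug with at least \code{min_exposed} exposed reports, builds
#' the 2x2 table of exposure by event over the whole corpus and computes
#' the reporting odds ratio, its 95\% confidence interval and Wald Z-score
#' via [ror_z()].  Results are sorted by |Z| descending, which makes the
#' output invariant to input report order.
#'
#' @param reports Deduplicated, drug-name-normalized report data.frame.
#' @param event_terms Preferred-term set defining the event.
#' @param min_exposed Minimum exposed-report count for a drug to be
#'   screened (default 100; thousands of rare drugs otherwise produce
#'   uninformative wide intervals).
#' @return Data.frame of signal rows (label, a, b, c, d, ror, ci_low,
#'   ci_high, z, n_exposed).
#' @export
drug_event_screen <- function(reports, event_terms, min_exposed = 100) {
  check_report_columns(reports)
  flags <- flag_events(reports, event_terms)
  drug_lists <- split_terms(reports$drugs)
  counts <- drug_event_counts(drug_lists, flags)
  screen_rows(counts, n_total = nrow(reports), n_event = sum(flags),
              min_exposed = min_exposed)
}

#' Concomitant-drug mitigation screen within an index-drug cohort
#'
#' Restricts the corpus to reports exposed to \code{index_drug} and runs a
#' second-layer disproportionality screen of every co-reported drug
#' against the event inside that cohort.  A co-drug whose 95\% confidence
#' interval lies entirely below 1 is flagged as a candidate mitigator
#' (\code{mitigator} column); the |Z| ranking is also returned so callers
#' can instead rank low-ROR drugs by significance.
#'
#' @param reports Deduplicated, normalized report data.frame.
#' @param index_drug Generic name of the index drug.
#' @param event_terms Preferred-term set defining the event.
#' @param min_exposed Minimum co-exposed count (default 10).
#' @return Data.frame of signal rows plus a logical \code{mitigator}
#'   column.
#' @export
concomitant_screen <- function(reports, index_drug, event_terms,
                               min_exposed = 10) {
  check_report_columns(reports)
  index_drug <- normalize_term(index_drug)
  drug_lists <- split_terms(reports$drugs)
  in_cohort <- vapply(drug_lists, function(v) index_drug %in% v, logical(1))
  if (!any(in_cohort)) stop("index drug absent from corpus: ", index_drug)
  cohort <- reports[in_cohort, , drop = FALSE]
  flags <- flag_events(cohort, event_terms)
  co_lists <- lapply(drug_lists[in_cohort], setdiff, y = index_drug)
  counts <- drug_event_counts(co_lists, flags)
  res <- screen_rows(counts, n_total = nrow(cohort), n_event = sum(flags),
                     min_exposed = min_exposed)
  res$mitigator <- res$ci_high < 1
  res
}

#' Volcano-plot coordinates for a set of signal results
#'
#' One row per signal: x = ln(ROR), y = |Z|, with the exposed-report count
#' as the size key, matching the conventional volcano display of
#' disproportionality screens.
#'
#' @param results Data.frame of signal rows as returned by the screens.
#' @return Data.frame with columns label, log_ror, abs_z, n_exposed.
#' @export
volcano_table <- function(results) {
  if (nrow(results) == 0) stop("no signal results to plot")
  data.frame(label = results$label,
             log_ror = log(results$ror),
             abs_z = abs(results$z),
             n_exposed = results$n_exposed,
             stringsAsFactors = FALSE)
}
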