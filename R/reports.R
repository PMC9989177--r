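# Spontaneous-report handling: parsing, drug-name normalization,
# case-level deduplication and adverse-event flagging.
#
# A report table is a data.frame with columns report_id, case_id, version
# (orderable within a case), drugs and events; the latter two are
# pipe-delimited term lists.  Terms are matched case-insensitively after
# trimming, so all internal comparisons run on normalized strings.

normalize_term <- function(x) tolower(trimws(x))

split_terms <- function(x) {
  out <- strsplit(as.character(x), "|", fixed = TRUE)
  lapply(out, function(v) unique(normalize_term(v[nzchar(trimws(v))])))
}

join_terms <- function(lst) {
  vapply(lst, paste, character(1), collapse = "|")
}

check_report_columns <- function(reports) {
  needed <- base::c("report_id", "case_id", "version", "drugs", "events")
  missing <- setdiff(needed, names(reports))
  if (length(missing)) {
    stop("report table lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(reports)
}

#' Normalize free-text drug names to unified generic names
#'
#' Spontaneous reports carry trade names, abbreviations and misspellings;
#' a curated many-to-one map (raw name -> generic name) collapses them.
#' Names absent from the map are retained verbatim (after lower-casing and
#' trimming) with a single summary warning, rather than being dropped.
#'
#' @param reports Report data.frame (see package readers).
#' @param drug_map Data.frame with columns \code{raw_name} and
#'   \code{generic_name}.
#' @return The report table with its \code{drugs} column rewritten.
#' @export
normalize_drug_names <- function(reports, drug_map) {
  check_report_columns(reports)
  if (!all(base::c("raw_name", "generic_name") %in% names(drug_map))) {
    stop("drug map needs columns raw_name and generic_name")
  }
  map <- stats::setNames(normalize_term(drug_map$generic_name),
                         normalize_term(drug_map$raw_name))
  lists <- split_terms(reports$drugs)
  unmapped <- character(0)
  lists <- lapply(lists, function(v) {
    hit <- map[v]
    miss <- is.na(hit)
    if (any(miss)) {
      unmapped <<- base::c(unmapped, v[miss])
      hit[miss] <- v[miss]
    }
    unique(unname(hit))
  })
  if (length(unmapped)) {
    warning(sprintf("%d drug name(s) not in the map retained verbatim (e.g. %s)",
                    length(unique(unmapped)),
                    paste(utils::head(unique(unmapped), 3), collapse = ", ")))
  }
  reports$drugs <- join_terms(lists)
  reports
}

#' Deduplicate spontaneous reports to one row per case
#'
#' Spontaneous-report databases store successive versions of the same
#' case under a shared case identifier.  Within each case the row with the
#' maximal version stamp is kept (the most recent information); version
#' ties are broken by keeping the smallest report_id, with a warning when
#' tied rows disagree in content.  The result is ordered by case_id, so
#' the operation is idempotent and input-order invariant.
#'
#' @param reports Report data.frame.
#' @return Deduplicated report data.frame, one row per case_id.
#' @export
deduplicate_reports <- function(reports) {
  check_report_columns(reports)
  if (nrow(reports) == 0) return(reports)
  ord <- order(reports$case_id, -xtfrm(reports$version), reports$report_id)
  sorted <- reports[ord, , drop = FALSE]
  first <- !duplicated(sorted$case_id)
  kept <- sorted[first, , drop = FALSE]
  # warn when a version tie carried conflicting drug/event content
  dup_ver <- duplicated(sorted[, base::c("case_id", "version")]) |
    duplicated(sorted[, base::c("case_id", "version")], fromLast = TRUE)
  if (any(dup_ver)) {
    tied <- sorted[dup_ver, , drop = FALSE]
    conflict <- any(stats::ave(paste(tied$drugs, tied$events),
                               tied$case_id, tied$version,
                               FUN = function(v) length(unique(v)) > 1) == "TRUE")
    if (conflict) {
      warning("tied versions with conflicting content; keeping first report_id")
    }
  }
  rownames(kept) <- NULL
  kept
}

#' Flag reports matching an adverse-event definition
#'
#' An event definition is a non-empty set of preferred terms; a report is
#' flagged when its event-term set intersects the definition.  Matching is
#' exact on lower-cased, trimmed terms (no fuzzy matching).
#'
#' @param reports Report data.frame.
#' @param event_terms Character vector of preferred terms.
#' @return Logical vector aligned with the rows of \code{reports}.
#' @export
flag_events <- function(reports, event_terms) {
  check_report_columns(reports)
  event_terms <- unique(normalize_term(event_terms[nzchar(trimws(event_terms))]))
  if (length(event_terms) == 0) stop("event definition has an empty term set")
  lists <- split_terms(reports$events)
  vapply(lists, function(v) any(v %in% event_terms), logical(1))
}
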