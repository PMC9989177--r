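# EHR trajectory analysis: quarterly checkpoint extraction over the first
# year of exposure, last-observation-carried-forward imputation and
# per-checkpoint within/between-group comparisons.

CHECKPOINT_MONTHS <- base::c(3, 6, 9, 12)
DAYS_PER_MONTH <- 30.4375  # mean calendar month; configurable per call

value_cols <- function() paste0("m", base::c(0, CHECKPOINT_MONTHS))
flag_cols <- function() paste0("imputed_m", CHECKPOINT_MONTHS)

#' Extract quarterly checkpoint series from dated laboratory values
#'
#' Per patient: the baseline (month 0) is the measurement nearest before
#' or on the index date within the 12-month pre-window; each checkpoint
#' (months 3, 6, 9, 12) takes the latest-dated measurement inside its
#' half-open window ((0,3], (3,6], (6,9], (9,12] months after index) --
#' the reading furthest from the index within the quarter.  Same-day
#' duplicates are averaged.  Patients without a baseline are excluded
#' (ids in the \code{"excluded"} attribute, reported via \code{message}).
#'
#' @param labs Long lab data.frame (patient_id, analyte, value, date).
#' @param index_dates Named vector/list of index dates keyed by
#'   patient_id, or a data.frame with patient_id and index_date.
#' @param analyte Analyte name.
#' @param days_per_month Days per month used to place window boundaries
#'   (default 30.4375).
#' @return Data.frame with one row per retained patient: patient_id,
#'   m0, m3, m6, m9, m12 (NA when the window was empty) and
#'   imputed_m* flags (all FALSE before imputation).
#' @export
checkpoint_series <- function(labs, index_dates, analyte,
                              days_per_month = DAYS_PER_MONTH) {
  if (is.data.frame(index_dates)) {
    index_dates <- stats::setNames(index_dates$index_date,
                                   index_dates$patient_id)
  }
  lab <- labs[labs$analyte == analyte & !is.na(labs$value), , drop = FALSE]
  lab <- lab[as.character(lab$patient_id) %in% names(index_dates), ,
             drop = FALSE]
  by_pat <- split(lab, as.character(lab$patient_id))
  excluded <- character(0)
  rows <- lapply(names(index_dates), function(pid) {
    d <- by_pat[[pid]]
    idx <- as.numeric(index_dates[[pid]])
    vals <- rep(NA_real_, 5)
    if (!is.null(d)) {
      off <- as.numeric(d$date) - idx
      base_win <- off > -12 * days_per_month & off <= 0
      if (any(base_win)) {
        best <- max(off[base_win])
        vals[1] <- mean(d$value[base_win & off == best])
      }
      for (k in seq_along(CHECKPOINT_MONTHS)) {
        lo <- (CHECKPOINT_MONTHS[k] - 3) * days_per_month
        hi <- CHECKPOINT_MONTHS[k] * days_per_month
        win <- off > lo & off <= hi
        if (any(win)) {
          best <- max(off[win])
          vals[k + 1] <- mean(d$value[win & off == best])
        }
      }
    }
    if (is.na(vals[1])) {
      excluded <<- base::c(excluded, pid)
      return(NULL)
    }
    out <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
    out[value_cols()] <- as.list(vals)
    out[flag_cols()] <- FALSE
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(patient_id = character(0))
    res[value_cols()] <- lapply(value_cols(), function(x) numeric(0))
    res[flag_cols()] <- lapply(flag_cols(), function(x) logical(0))
  }
  if (length(excluded)) {
    message(length(excluded), " patient(s) excluded: no baseline measurement")
  }
  attr(res, "excluded") <- excluded
  rownames(res) <- NULL
  res
}

#' Last-observation-carried-forward imputation of checkpoint series
#'
#' Each missing checkpoint takes the nearest earlier non-missing value
#' (baseline included) and its imputed flag is set.  Non-missing values
#' are never altered, so the operation is idempotent.
#'
#' @param series Checkpoint data.frame from [checkpoint_series()].
#' @return The series with all checkpoints filled and flags updated.
#' @export
locf_impute <- function(series) {
  vc <- value_cols(); fc <- flag_cols()
  if (any(is.na(series[[vc[1]]]))) stop("baseline (m0) must be non-missing")
  for (k in 2:length(vc)) {
    miss <- is.na(series[[vc[k]]])
    if (any(miss)) {
      series[[vc[k]]][miss] <- series[[vc[k - 1]]][miss]
      series[[fc[k - 1]]][miss] <- TRUE
    }
  }
  series
}

#' Compare lipid trajectories between two groups at each checkpoint
#'
#' At each checkpoint month the within-group change from baseline is
#' tested by a paired t-test (per group) and the two groups are compared
#' by Welch's t-test on the checkpoint values; imputed values enter both,
#' consistent with LOCF semantics.  Month 0 rows carry the baseline
#' summaries with the between-group test only.
#'
#' @param group_a,group_b Imputed checkpoint data.frames (e.g. exposed
#'   without / with a candidate mitigating co-medication).
#' @param labels Length-2 character vector of group labels.
#' @return Data.frame (group, month, n, mean, sem, paired_p, between_p).
#' @export
trajectory_compare <- function(group_a, group_b,
                               labels = base::c("group_a", "group_b")) {
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop("each group needs at least 2 complete series")
  }
  vc <- value_cols()
  months <- base::c(0, CHECKPOINT_MONTHS)
  rows <- list()
  for (k in seq_along(vc)) {
    va <- group_a[[vc[k]]]; vb <- group_b[[vc[k]]]
    if (anyNA(va) || anyNA(vb)) {
      stop("series contain missing checkpoints; run locf_impute() first")
    }
    between <- if (identical(va, vb)) 1 else welch_t(va, vb)$p_value
    for (side in 1:2) {
      v <- if (side == 1) va else vb
      b0 <- if (side == 1) group_a[[vc[1]]] else group_b[[vc[1]]]
      paired_p <- if (k == 1) NA_real_ else paired_t(b0, v)$p_value
      rows[[length(rows) + 1]] <- data.frame(
        group = labels[side], month = months[k], n = length(v),
        mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
        paired_p = paired_p, between_p = between,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
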