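# Claims-cohort analysis: pre/post laboratory selection around an index
# prescription, propensity-score estimation, greedy 1:1 matching,
# baseline balance and paired pre/post effect estimation.
#
# Patients arrive as one row per patient (patient_id, covariate columns,
# treated flag, index_date); laboratory values arrive long
# (patient_id, analyte, value, date).  Dates are Date or numeric-day
# scalars; only differences are used.

#' Select the pre/post laboratory pair for one patient
#'
#' The pre value is the measurement nearest before (or on) the index
#' date within \code{window_days}; the post value is the earliest
#' measurement after the index date within \code{window_days}.  A
#' measurement exactly on the index date counts as pre.  Same-day
#' duplicates are averaged with a warning.
#'
#' @param labs Long lab data.frame for one patient (columns analyte,
#'   value, date).
#' @param index_date Index prescription date.
#' @param analyte Analyte name to select.
#' @param window_days Window half-width in days (default 365).
#' @return One-row data.frame (pre_value, pre_date, post_value,
#'   post_date) or \code{NULL} when either window is empty.
#' @export
select_pre_post <- function(labs, index_date, analyte, window_days = 365) {
  lab <- labs[labs$analyte == analyte & !is.na(labs$value), , drop = FALSE]
  if (nrow(lab) == 0) return(NULL)
  off <- as.numeric(lab$date) - as.numeric(index_date)
  pre <- lab[off > -window_days & off <= 0, , drop = FALSE]
  post <- lab[off > 0 & off <= window_days, , drop = FALSE]
  if (nrow(pre) == 0 || nrow(post) == 0) return(NULL)
  take <- function(d, which_date) {
    target <- if (which_date == "latest") max(as.numeric(d$date))
              else min(as.numeric(d$date))
    hit <- d[as.numeric(d$date) == target, , drop = FALSE]
    if (nrow(hit) > 1) {
      warning("multiple labs on the selected date; averaging")
    }
    list(value = mean(hit$value), date = hit$date[1])
  }
  p1 <- take(pre, "latest")
  p2 <- take(post, "earliest")
  data.frame(pre_value = p1$value, pre_date = p1$date,
             post_value = p2$value, post_date = p2$date)
}

#' Collect pre/post records for a whole cohort
#'
#' Applies [select_pre_post()] per patient and binds the complete records.
#'
#' @param patients Patient data.frame with patient_id and index_date.
#' @param labs Long lab data.frame (patient_id, analyte, value, date).
#' @param analyte Analyte name.
#' @param window_days Window half-width in days.
#' @return Data.frame (patient_id, pre_value, pre_date, post_value,
#'   post_date); patients with an empty window are omitted.
#' @export
collect_pre_post <- function(patients, labs, analyte, window_days = 365) {
  labs_by_pat <- split(labs, labs$patient_id)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    lab <- labs_by_pat[[as.character(pid)]]
    if (is.null(lab)) return(NULL)
    rec <- select_pre_post(lab, patients$index_date[i], analyte, window_days)
    if (is.null(rec)) return(NULL)
    cbind(data.frame(patient_id = pid), rec)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), pre_value = numeric(0),
                      pre_date = numeric(0), post_value = numeric(0),
                      post_date = numeric(0))
  }
  out
}

#' Estimate propensity scores for treatment
#'
#' Logistic regression of the treated flag on the configured covariates
#' via [logistic_fit()].  Patients with any missing model covariate are
#' excluded before fitting (their ids are attached as the
#' \code{"excluded"} attribute and reported via \code{message}).
#'
#' @param patients Patient data.frame with a \code{treated} column.
#' @param covariate_names Covariate column names entering the model.
#' @return Data.frame (patient_id, treated, score) for scored patients,
#'   with attributes \code{"fit"} (the [logistic_fit()] result) and
#'   \code{"excluded"}.
#' @export
propensity_scores <- function(patients, covariate_names) {
  missing_cols <- setdiff(covariate_names, names(patients))
  if (length(missing_cols)) {
    stop("patient table lacks covariate(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(patients[, covariate_names, drop = FALSE])
  complete <- stats::complete.cases(x) & !is.na(patients$treated)
  if (any(!complete)) {
    message(sum(!complete), " patient(s) excluded for missing covariates")
  }
  fit <- logistic_fit(x[complete, , drop = FALSE],
                      as.numeric(patients$treated[complete]))
  out <- data.frame(patient_id = patients$patient_id[complete],
                    treated = patients$treated[complete],
                    score = fit$fitted,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "excluded") <- patients$patient_id[!complete]
  out
}

#' Greedy 1:1 nearest-neighbour propensity matching
#'
#' Treated units are processed in descending propensity-score order (ties
#' broken by patient id); each takes the nearest unmatched control by
#' absolute score distance (control-id tie-break), without replacement.
#' With a caliper, treated units whose nearest free control is farther
#' than the caliper remain unmatched and are dropped with a message.
#' The procedure is deterministic given its inputs.
#'
#' @param scores Data.frame from [propensity_scores()] (patient_id,
#'   treated, score).
#' @param caliper Maximum allowed score distance (default \code{Inf}:
#'   no caliper).
#' @return Data.frame of pairs (treated_id, control_id, score_distance).
#' @export
greedy_match <- function(scores, caliper = Inf) {
  tr <- scores[scores$treated == 1 | scores$treated == TRUE, , drop = FALSE]
  ct <- scores[!(scores$treated == 1 | scores$treated == TRUE), , drop = FALSE]
  if (nrow(tr) == 0 || nrow(ct) == 0) {
    stop("need at least one treated and one control to match")
  }
  tr <- tr[order(-tr$score, tr$patient_id), , drop = FALSE]
  free <- rep(TRUE, nrow(ct))
  pairs <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (!any(free)) break
    dist <- abs(ct$score - tr$score[i])
    dist[!free] <- Inf
    j <- which(dist == min(dist))
    if (length(j) > 1) j <- j[order(ct$patient_id[j])][1]
    if (dist[j] > caliper) next
    pairs[[i]] <- data.frame(treated_id = tr$patient_id[i],
                             control_id = ct$patient_id[j],
                             score_distance = dist[j],
                             stringsAsFactors = FALSE)
    free[j] <- FALSE
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) stop("no pairs possible within the caliper")
  n_drop <- nrow(tr) - nrow(out)
  if (n_drop > 0) message(n_drop, " treated unit(s) unmatched and dropped")
  rownames(out) <- NULL
  out
}

smd <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  s <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (s == 0) return(0)
  (m1 - m2) / s
}

#' Baseline balance table for a matched cohort
#'
#' Per covariate: group summaries (mean +/- SEM for continuous, count and
#' proportion for binary), a p-value (Welch t for continuous, Fisher
#' exact for binary) and the standardized mean difference.  Covariates
#' whose observed values all lie in \{0, 1\} are treated as binary.
#'
#' @param patients Patient data.frame.
#' @param pairs Matched pairs from [greedy_match()].
#' @param covariate_names Covariates to summarize.
#' @return Data.frame, one row per covariate.
#' @export
balance_table <- function(patients, pairs, covariate_names) {
  g1 <- patients[match(pairs$treated_id, patients$patient_id), , drop = FALSE]
  g2 <- patients[match(pairs$control_id, patients$patient_id), , drop = FALSE]
  rows <- lapply(covariate_names, function(cv) {
    x <- g1[[cv]]; y <- g2[[cv]]
    binary <- all(base::c(x, y) %in% base::c(0, 1))
    if (binary) {
      tab <- contingency_table(sum(x), length(x) - sum(x),
                               sum(y), length(y) - sum(y))
      p <- fisher_exact(tab)$p_value
      data.frame(covariate = cv, type = "binary",
                 treated_summary = sum(x) / length(x),
                 control_summary = sum(y) / length(y),
                 p_value = p,
                 smd = {
                   p1 <- mean(x); p2 <- mean(y)
                   s <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
                   if (s == 0) 0 else (p1 - p2) / s
                 },
                 stringsAsFactors = FALSE)
    } else {
      p <- if (identical(x, y)) 1 else welch_t(x, y)$p_value
      data.frame(covariate = cv, type = "continuous",
                 treated_summary = mean(x),
                 control_summary = mean(y),
                 p_value = p,
                 smd = smd(x, y),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pre/post treatment-effect analysis on a matched cohort
#'
#' Within each group (treated, control) the pre-index value is compared
#' with the post-index value by a paired t-test; between groups the
#' change scores (post - pre) are compared by Welch's t-test.
#'
#' @param patients Patient data.frame (treated flag, index_date).
#' @param labs Long lab data.frame.
#' @param analyte Analyte name.
#' @param window_days Pre/post window half-width in days.
#' @return List with \code{groups} (data.frame: group, n, pre_mean,
#'   post_mean, mean_change, paired_p) and \code{between_p}.
#' @export
pre_post_effect <- function(patients, labs, analyte, window_days = 365) {
  treated_flag <- patients$treated == 1 | patients$treated == TRUE
  groups <- list(treated = patients[treated_flag, , drop = FALSE],
                 control = patients[!treated_flag, , drop = FALSE])
  changes <- list()
  rows <- lapply(names(groups), function(g) {
    rec <- collect_pre_post(groups[[g]], labs, analyte, window_days)
    if (nrow(rec) < 2) {
      stop("fewer than 2 complete pre/post pairs in group: ", g)
    }
    pt <- paired_t(rec$pre_value, rec$post_value)
    changes[[g]] <<- rec$post_value - rec$pre_value
    data.frame(group = g, n = nrow(rec),
               pre_mean = mean(rec$pre_value),
               post_mean = mean(rec$post_value),
               mean_change = mean(rec$post_value - rec$pre_value),
               paired_p = pt$p_value,
               stringsAsFactors = FALSE)
  })
  list(groups = do.call(rbind, rows),
       between_p = welch_t(changes$treated, changes$control)$p_value)
}
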