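# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: spontaneous reports with a planted drug-event
# odds elevation and co-drug mitigation, claims cohorts with a known
# treatment-assignment model and planted pre/post shifts, sparse EHR
# trajectories with group-specific drift, and Poisson/negative-binomial
# count matrices with planted fold-changes.  Every generator is a pure
# function of its arguments: identical seeds give identical tables, and a
# truth record carrying the planted parameters is attached to the output.

# Deterministic sub-seed derivation so that each table draws from its own
# stream (kept below 2^31 - 1).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 1299709) %% 2147483647
}

DEFAULT_DRUG_PROBS <- base::c(
  olanzapine = 0.05, "vitamin d" = 0.04, metformin = 0.08,
  aspirin = 0.15, quetiapine = 0.04, lisinopril = 0.10,
  omeprazole = 0.12, sertraline = 0.06, atorvastatin = 0.09,
  levothyroxine = 0.07, ibuprofen = 0.12, gabapentin = 0.05)

DYSLIPIDEMIA_TERMS <- base::c(
  "dyslipidaemia", "blood cholesterol increased", "hyperlipidaemia",
  "blood triglycerides increased", "low density lipoprotein increased",
  "high density lipoprotein decreased")

OTHER_TERMS <- base::c("nausea", "headache", "dizziness", "fatigue",
                       "rash", "insomnia")

#' Generate a synthetic spontaneous-report corpus with planted signals
#'
#' Drug exposures are independent Bernoulli draws from the catalogue;
#' the adverse-event odds are multiplied by \code{index_or} when the
#' index drug is present and additionally by \code{mitigation_or} when
#' both the index drug and the co-drug are present (the mitigation acts
#' only inside the index cohort, mirroring a concomitant-drug rescue).
#' Flagged reports receive a random event preferred term; background
#' reports may carry unrelated terms.  A fraction of cases is injected as
#' an extra earlier version, exercising deduplication.
#'
#' @param n_reports Number of cases.
#' @param event_prob Background event probability.
#' @param drug_probs Named vector of per-drug exposure probabilities.
#' @param index_drug,co_drug Names (within the catalogue) of the planted
#'   index drug and mitigating co-drug.
#' @param index_or Planted odds multiplier for the index drug.
#' @param mitigation_or Planted odds multiplier for the co-drug within
#'   the index cohort.
#' @param duplicate_rate Fraction of cases receiving an injected earlier
#'   version.
#' @param seed Mandatory integer seed.
#' @return Report data.frame (report_id, case_id, version, drugs,
#'   events) with a \code{"truth"} attribute (planted parameters and
#'   injected duplicate case ids).
#' @export
gen_reports <- function(n_reports = 50000, event_prob = 0.01,
                        drug_probs = DEFAULT_DRUG_PROBS,
                        index_drug = "olanzapine", co_drug = "vitamin d",
                        index_or = 8, mitigation_or = 0.5,
                        duplicate_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(event_prob > 0, event_prob < 1, all(drug_probs > 0),
            all(drug_probs < 1), index_or > 0, mitigation_or > 0,
            duplicate_rate >= 0, duplicate_rate < 1)
  set.seed(derive_seed(seed, 1))
  k <- length(drug_probs)
  expo <- matrix(stats::rbinom(n_reports * k, 1,
                               rep(drug_probs, each = n_reports)),
                 nrow = n_reports)
  colnames(expo) <- names(drug_probs)
  # guarantee a non-empty drug list per report
  empty <- rowSums(expo) == 0
  if (any(empty)) {
    expo[cbind(which(empty),
               sample.int(k, sum(empty), replace = TRUE))] <- 1
  }
  idx <- expo[, index_drug] == 1
  co <- expo[, co_drug] == 1
  odds <- event_prob / (1 - event_prob) *
    ifelse(idx, index_or, 1) * ifelse(idx & co, mitigation_or, 1)
  event <- stats::rbinom(n_reports, 1, odds / (1 + odds)) == 1

  drug_names <- colnames(expo)
  drugs <- apply(expo == 1, 1, function(r) paste(drug_names[r], collapse = "|"))
  events <- character(n_reports)
  events[event] <- sample(DYSLIPIDEMIA_TERMS, sum(event), replace = TRUE)
  noise <- stats::rbinom(n_reports, 1, 0.3) == 1
  other <- sample(OTHER_TERMS, n_reports, replace = TRUE)
  events <- ifelse(noise,
                   ifelse(nzchar(events), paste(events, other, sep = "|"),
                          other),
                   events)
  reports <- data.frame(
    report_id = sprintf("R%07d", seq_len(n_reports)),
    case_id = sprintf("C%07d", seq_len(n_reports)),
    version = 2L, drugs = drugs, events = events,
    stringsAsFactors = FALSE)

  dup_cases <- character(0)
  if (duplicate_rate > 0) {
    n_dup <- floor(duplicate_rate * n_reports)
    pick <- sample.int(n_reports, n_dup)
    dups <- reports[pick, , drop = FALSE]
    dups$version <- 1L
    dups$report_id <- sprintf("R%07dv1", pick)
    dups$events <- ""   # earlier, less complete version
    dup_cases <- dups$case_id
    reports <- rbind(reports, dups)
    reports <- reports[sample.int(nrow(reports)), , drop = FALSE]
    rownames(reports) <- NULL
  }
  attr(reports, "truth") <- list(
    event_prob = event_prob, index_drug = index_drug, co_drug = co_drug,
    index_or = index_or, mitigation_or = mitigation_or,
    duplicate_case_ids = dup_cases, n_cases = n_reports)
  reports
}

DEFAULT_COVARIATES <- list(
  elderly = list(type = "binary", prob = 0.05),
  female = list(type = "binary", prob = 0.90),
  schizophrenia = list(type = "binary", prob = 0.28),
  antipsychotics = list(type = "binary", prob = 0.38),
  glucose = list(type = "continuous", mean = 92, sd = 12, min = 50),
  hba1c = list(type = "continuous", mean = 5.5, sd = 0.4, min = 3),
  bmi = list(type = "continuous", mean = 20, sd = 3, min = 12))

DEFAULT_SHIFTS <- list(
  triglyceride = base::c(control = 0, treated = 0),
  ldl = base::c(control = 11, treated = 0),
  hdl = base::c(control = -5, treated = 4))

DEFAULT_BASELINES <- base::c(triglyceride = 90, ldl = 119, hdl = 70)

#' Generate a synthetic claims cohort with a known assignment model
#'
#' Covariates are drawn from the configured distributions (binary
#' prevalences and truncated Gaussians at magnitudes typical of a lipid
#' cohort); the treated flag follows a logistic model with the supplied
#' coefficients; each analyte gets one pre-index and one post-index lab
#' whose post value carries the planted group-specific shift.  Visit
#' dates are uniform within the 12-month windows and pre/post labs drop
#' out independently at \code{missing_rate}.
#'
#' @param n_patients Cohort size.
#' @param covariates Named list of covariate specs (\code{type} plus
#'   \code{prob} or \code{mean}/\code{sd}/\code{min}).
#' @param assignment_coefs Named numeric vector: \code{intercept} plus
#'   coefficients on covariate names.
#' @param shifts Named list per analyte of planted post-index shifts,
#'   each \code{c(control=, treated=)} in analyte units.
#' @param baselines Named vector of analyte baseline means.
#' @param baseline_sd Between-patient baseline SD (analyte units).
#' @param noise_sd Within-patient measurement SD.
#' @param missing_rate Probability that a pre or post lab is missing.
#' @param seed Mandatory integer seed.
#' @return List with \code{patients}, long \code{labs} and \code{truth}.
#' @export
gen_claims_cohort <- function(n_patients = 1000,
                              covariates = DEFAULT_COVARIATES,
                              assignment_coefs = base::c(intercept = -2,
                                                         female = 1.2,
                                                         elderly = 1.0),
                              shifts = DEFAULT_SHIFTS,
                              baselines = DEFAULT_BASELINES,
                              baseline_sd = 25, noise_sd = 15,
                              missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(baseline_sd > 0, noise_sd > 0,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(derive_seed(seed, 2))
  cov_df <- as.data.frame(lapply(covariates, function(sp) {
    if (sp$type == "binary") {
      stats::rbinom(n_patients, 1, sp$prob)
    } else {
      pmax(stats::rnorm(n_patients, sp$mean, sp$sd),
           if (is.null(sp$min)) -Inf else sp$min)
    }
  }))
  eta <- rep(assignment_coefs[["intercept"]], n_patients)
  for (nm in setdiff(names(assignment_coefs), "intercept")) {
    eta <- eta + assignment_coefs[[nm]] * cov_df[[nm]]
  }
  treated <- stats::rbinom(n_patients, 1, stats::plogis(eta))
  index_date <- as.numeric(sample.int(1000, n_patients, replace = TRUE))
  patients <- cbind(
    data.frame(patient_id = sprintf("P%05d", seq_len(n_patients)),
               stringsAsFactors = FALSE),
    cov_df,
    data.frame(treated = treated, index_date = index_date))

  lab_rows <- list()
  for (an in names(shifts)) {
    base_val <- stats::rnorm(n_patients, baselines[[an]], baseline_sd)
    shift <- ifelse(treated == 1, shifts[[an]][["treated"]],
                    shifts[[an]][["control"]])
    pre_off <- -sample.int(365, n_patients, replace = TRUE) + 1  # in (-365, 0]
    post_off <- sample.int(365, n_patients, replace = TRUE)      # in (0, 365]
    pre_val <- base_val + stats::rnorm(n_patients, 0, noise_sd)
    post_val <- base_val + shift + stats::rnorm(n_patients, 0, noise_sd)
    keep_pre <- stats::runif(n_patients) >= missing_rate
    keep_post <- stats::runif(n_patients) >= missing_rate
    lab_rows[[an]] <- rbind(
      data.frame(patient_id = patients$patient_id[keep_pre], analyte = an,
                 value = pre_val[keep_pre],
                 date = index_date[keep_pre] + pre_off[keep_pre],
                 stringsAsFactors = FALSE),
      data.frame(patient_id = patients$patient_id[keep_post], analyte = an,
                 value = post_val[keep_post],
                 date = index_date[keep_post] + post_off[keep_post],
                 stringsAsFactors = FALSE))
  }
  labs <- do.call(rbind, lab_rows)
  rownames(labs) <- NULL
  list(patients = patients, labs = labs,
       truth = list(assignment_coefs = assignment_coefs, shifts = shifts,
                    baselines = baselines, noise_sd = noise_sd))
}

#' Generate sparse quarterly EHR lab series with group-specific drift
#'
#' Two groups of patients with a baseline draw before the index date and
#' scheduled quarterly follow-up visits: each checkpoint visit occurs
#' with probability \code{visit_prob} and is dated at the checkpoint
#' minus up to 14 days of jitter, emulating routine follow-up
#' phlebotomy.  Values follow baseline + slope x month-at-visit + noise,
#' with the slope differing by group (drift in one, flat in the other,
#' mirroring an exposed cohort with and without a mitigating
#' co-medication).
#'
#' @param n_a,n_b Group sizes.
#' @param slope_a,slope_b Drift in analyte units per month.
#' @param baseline_mean,baseline_sd Baseline distribution.
#' @param noise_sd Measurement noise SD.
#' @param visit_prob Per-window visit probability (1 = dense sampling,
#'   no imputation needed).
#' @param analyte Analyte label written to the lab table.
#' @param seed Mandatory integer seed.
#' @return List with long \code{labs}, \code{groups} (patient_id,
#'   group), \code{index_dates} and \code{truth}.
#' @export
gen_ehr_series <- function(n_a = 400, n_b = 23, slope_a = 4.5,
                           slope_b = 0, baseline_mean = 120,
                           baseline_sd = 40, noise_sd = 20,
                           visit_prob = 0.8, analyte = "triglyceride",
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_a >= 2, n_b >= 2, baseline_sd > 0, noise_sd > 0,
            visit_prob > 0, visit_prob <= 1)
  set.seed(derive_seed(seed, 3))
  n <- n_a + n_b
  ids <- sprintf("E%05d", seq_len(n))
  group <- rep(base::c("a", "b"), base::c(n_a, n_b))
  slope <- ifelse(group == "a", slope_a, slope_b)
  base_val <- stats::rnorm(n, baseline_mean, baseline_sd)
  index_dates <- stats::setNames(rep(0, n), ids)
  rows <- list()
  # baseline draw within 90 days before index
  b_off <- -stats::runif(n, 0, 90)
  rows[[1]] <- data.frame(patient_id = ids, analyte = analyte,
                          value = base_val + stats::rnorm(n, 0, noise_sd),
                          date = b_off, stringsAsFactors = FALSE)
  for (m in CHECKPOINT_MONTHS) {
    visit <- stats::runif(n) < visit_prob
    day <- m * DAYS_PER_MONTH - stats::runif(n, 0, 14)
    month_at <- day / DAYS_PER_MONTH
    val <- base_val + slope * month_at + stats::rnorm(n, 0, noise_sd)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = ids[visit], analyte = analyte, value = val[visit],
      date = day[visit], stringsAsFactors = FALSE)
  }
  labs <- do.call(rbind, rows)
  rownames(labs) <- NULL
  list(labs = labs,
       groups = data.frame(patient_id = ids, group = group,
                           stringsAsFactors = FALSE),
       index_dates = index_dates,
       truth = list(slope_a = slope_a, slope_b = slope_b,
                    baseline_mean = baseline_mean, noise_sd = noise_sd))
}

#' Generate a two-condition count matrix with planted fold-changes
#'
#' Per-gene expression weights are log-normal; counts are Poisson (or
#' negative binomial when \code{dispersion > 0}) around expected counts
#' proportional to the weights, scaled to the library size.  A random
#' subset of genes carries a planted fold-change in condition b, with
#' random up/down direction.
#'
#' @param n_genes Number of genes.
#' @param lib_size Expected library size per sample.
#' @param n_per_condition Samples per condition.
#' @param de_fraction Fraction of genes with a planted fold-change.
#' @param fold Planted fold-change (> 1).
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param seed Mandatory integer seed.
#' @return List with \code{counts} (rownames g0001...), \code{lengths},
#'   \code{sample_conditions} and \code{truth} (planted gene ids and
#'   directions).
#' @export
gen_counts <- function(n_genes = 5000, lib_size = 1e6,
                       n_per_condition = 1, de_fraction = 0.004,
                       fold = 4, dispersion = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes > 1, lib_size > 0, de_fraction >= 0, de_fraction <= 1,
            fold > 0, dispersion >= 0)
  set.seed(derive_seed(seed, 4))
  genes <- sprintf("g%05d", seq_len(n_genes))
  w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  n_de <- round(de_fraction * n_genes)
  planted <- sort(sample.int(n_genes, n_de))
  dir_up <- stats::rbinom(n_de, 1, 0.5) == 1
  w_b <- w
  w_b[planted] <- w[planted] * ifelse(dir_up, fold, 1 / fold)
  draw <- function(wv) {
    mu <- wv / sum(wv) * lib_size
    sapply(seq_len(n_per_condition), function(j) {
      if (dispersion > 0) {
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(n_genes, mu)
      }
    })
  }
  counts <- cbind(draw(w), draw(w_b))
  rownames(counts) <- genes
  colnames(counts) <- base::c(paste0("a_", seq_len(n_per_condition)),
                              paste0("b_", seq_len(n_per_condition)))
  cond <- stats::setNames(rep(base::c("a", "b"), each = n_per_condition),
                          colnames(counts))
  lengths <- stats::setNames(sample(500:3000, n_genes, replace = TRUE),
                             genes)
  list(counts = counts, lengths = lengths, sample_conditions = cond,
       truth = list(planted = genes[planted],
                    direction = ifelse(dir_up, "up", "down"),
                    fold = fold, dispersion = dispersion))
}
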