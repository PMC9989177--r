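# Claims-cohort machinery: pre/post lab selection, propensity scoring,
# greedy matching, balance and paired effects.

test_that("pre/post selection respects window boundaries exactly", {
  labs <- data.frame(patient_id = "p1", analyte = "ldl",
                     value = c(90, 100, 110, 120, 130),
                     date = c(-400, -30, 0, 1, 10))
  # lab at -400 is outside the pre window; day 0 (index) counts as pre;
  # day 1 counts as post
  rec <- select_pre_post(labs, index_date = 0, analyte = "ldl")
  expect_equal(rec$pre_value, 110)
  expect_equal(rec$pre_date, 0)
  expect_equal(rec$post_value, 120)
  expect_equal(rec$post_date, 1)

  # no post-window lab: record missing
  pre_only <- labs[labs$date <= 0, ]
  expect_null(select_pre_post(pre_only, 0, "ldl"))

  # same-day duplicates averaged with a warning
  tie <- data.frame(patient_id = "p1", analyte = "ldl",
                    value = c(100, 110, 120), date = c(-5, -5, 30))
  expect_warning(rec2 <- select_pre_post(tie, 0, "ldl"), "averaging")
  expect_equal(rec2$pre_value, 105)
})

test_that("propensity scores recover a planted assignment model", {
  sim <- gen_claims_cohort(n_patients = 5000,
                           assignment_coefs = c(intercept = -2,
                                                female = 1.5,
                                                elderly = 1.0),
                           seed = 31)
  sc <- propensity_scores(sim$patients, c("female", "elderly"))
  fit <- attr(sc, "fit")
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - (-2)) / 2, 0.15)
  expect_lt(abs(fit$coefficients[["female"]] - 1.5) / 1.5, 0.15)
  expect_lt(abs(fit$coefficients[["elderly"]] - 1.0) / 1.0, 0.30)
  expect_true(all(sc$score > 0 & sc$score < 1))
})

test_that("treatment independent of covariates gives flat scores", {
  sim <- gen_claims_cohort(n_patients = 3000,
                           assignment_coefs = c(intercept = -1),
                           seed = 32)
  sc <- propensity_scores(sim$patients, c("female", "elderly", "glucose"))
  prev <- mean(sim$patients$treated)
  expect_lt(abs(mean(sc$score) - prev), 0.01)
  expect_lt(sd(sc$score), 0.05)
})

test_that("patients with missing covariates are excluded from scoring", {
  sim <- gen_claims_cohort(n_patients = 200, seed = 33)
  sim$patients$glucose[c(3, 7)] <- NA
  expect_message(sc <- propensity_scores(sim$patients,
                                         c("female", "glucose")),
                 "2 patient")
  expect_equal(nrow(sc), 198)
  expect_setequal(attr(sc, "excluded"), sim$patients$patient_id[c(3, 7)])
})

test_that("greedy matching follows the stated order and caliper rules", {
  sc <- data.frame(patient_id = c("t1", "t2", "c1", "c2", "c3"),
                   treated = c(1, 1, 0, 0, 0),
                   score = c(0.2, 0.8, 0.25, 0.5, 0.9))
  pairs <- greedy_match(sc)
  # hand-run: treated 0.8 first takes 0.9; then 0.2 takes 0.25
  expect_equal(pairs$treated_id, c("t2", "t1"))
  expect_equal(pairs$control_id, c("c3", "c1"))
  expect_equal(pairs$score_distance, c(0.1, 0.05), tolerance = 1e-12)

  # identical score multisets: all distances zero
  sc2 <- data.frame(patient_id = c("t1", "t2", "c1", "c2"),
                    treated = c(1, 1, 0, 0),
                    score = c(0.3, 0.6, 0.6, 0.3))
  expect_true(all(greedy_match(sc2)$score_distance == 0))

  # caliper excludes a distant treated unit
  sc3 <- data.frame(patient_id = c("t1", "c1"), treated = c(1, 0),
                    score = c(0.5, 0.55))
  expect_error(greedy_match(sc3, caliper = 0.01), "no pairs")
  sc4 <- rbind(sc3, data.frame(patient_id = "t2", treated = 1,
                               score = 0.551))
  expect_message(p4 <- greedy_match(sc4, caliper = 0.01), "unmatched")
  expect_equal(p4$treated_id, "t2")

  # no control reuse; pair count bounded by both arms
  set.seed(34)
  sc5 <- data.frame(patient_id = sprintf("p%02d", 1:30),
                    treated = rep(c(1, 0), c(12, 18)),
                    score = runif(30))
  p5 <- greedy_match(sc5)
  expect_equal(nrow(p5), 12)
  expect_false(any(duplicated(p5$control_id)))
})

test_that("matching is invariant to relabeling of patient ids", {
  set.seed(35)
  sc <- data.frame(patient_id = sprintf("a%02d", 1:40),
                   treated = rep(c(1, 0), c(15, 25)),
                   score = round(runif(40), 3))
  p1 <- greedy_match(sc)
  sc2 <- sc
  sc2$patient_id <- sprintf("zz%02d", 1:40)  # order-preserving relabel
  p2 <- greedy_match(sc2)
  expect_equal(match(p1$treated_id, sc$patient_id),
               match(p2$treated_id, sc2$patient_id))
  expect_equal(match(p1$control_id, sc$patient_id),
               match(p2$control_id, sc2$patient_id))
})

test_that("matching improves covariate balance in a confounded cohort", {
  worse <- 0L
  for (s in 1:10) {
    sim <- gen_claims_cohort(n_patients = 1500,
                             assignment_coefs = c(intercept = -2.5,
                                                  female = 1.5,
                                                  elderly = 1.5),
                             seed = 400 + s)
    covs <- c("female", "elderly", "glucose", "bmi")
    sc <- propensity_scores(sim$patients, c("female", "elderly"))
    pairs <- greedy_match(sc)
    bal <- balance_table(sim$patients, pairs, covs)
    # pre-matching balance: treated vs all controls
    tr <- sim$patients[sim$patients$treated == 1, ]
    ct <- sim$patients[sim$patients$treated == 0, ]
    pre_smd <- vapply(covs, function(cv) {
      m1 <- mean(tr[[cv]]); m2 <- mean(ct[[cv]])
      s2 <- sqrt((var(tr[[cv]]) + var(ct[[cv]])) / 2)
      abs(m1 - m2) / s2
    }, numeric(1))
    if (max(abs(bal$smd)) < max(pre_smd)) worse <- worse + 1L
  }
  expect_gte(worse, 8L)
})

test_that("identical matched groups give p = 1 and zero SMD everywhere", {
  pat <- data.frame(patient_id = sprintf("p%02d", 1:8),
                    female = rep(c(1, 0, 1, 1), 2),
                    glucose = rep(c(90, 95, 100, 85), 2),
                    treated = rep(c(1, 0), each = 4),
                    index_date = 0)
  pairs <- data.frame(treated_id = sprintf("p%02d", 1:4),
                      control_id = sprintf("p%02d", 5:8),
                      score_distance = 0)
  bal <- balance_table(pat, pairs, c("female", "glucose"))
  expect_true(all(bal$p_value == 1))
  expect_true(all(bal$smd == 0))
})

test_that("pre/post effects recover planted shifts and degenerate cases", {
  sim <- gen_claims_cohort(n_patients = 1000, missing_rate = 0.1,
                           seed = 36)
  eff <- pre_post_effect(sim$patients, sim$labs, "ldl")
  ctrl <- eff$groups[eff$groups$group == "control", ]
  trt <- eff$groups[eff$groups$group == "treated", ]
  expect_lt(abs(ctrl$mean_change - 11), 3)
  expect_lt(abs(trt$mean_change - 0), 3)
  expect_lt(ctrl$paired_p, 0.05)

  # all post equal pre: paired statistic 0
  pat <- data.frame(patient_id = c("p1", "p2", "p3"), treated = c(1, 1, 0),
                    index_date = 0)
  labs <- data.frame(patient_id = rep(c("p1", "p2", "p3"), each = 2),
                     analyte = "ldl", value = rep(c(100, 120, 110), each = 2),
                     date = rep(c(-10, 10), 3))
  expect_error(pre_post_effect(pat, labs, "ldl"), "control")
})

test_that("paired pre/post testing holds its size under the null", {
  set.seed(37)
  reps <- 800
  rej <- 0L
  for (i in seq_len(reps)) {
    n <- 20
    pat <- data.frame(patient_id = sprintf("q%03d", 1:(2 * n)),
                      treated = rep(c(1, 0), each = n), index_date = 0)
    labs <- data.frame(
      patient_id = rep(pat$patient_id, each = 2),
      analyte = "ldl",
      value = 100 + rnorm(4 * n, 0, 15),
      date = rep(c(-20, 20), 2 * n))
    eff <- pre_post_effect(pat, labs, "ldl")
    if (eff$groups$paired_p[eff$groups$group == "control"] < 0.05) {
      rej <- rej + 1L
    }
  }
  expect_lte(rej / reps, 0.07)
})

test_that("a planted post shift is detected in the shifted group only", {
  # +11 mg/dL in the untreated group, noise SD 15, n = 20 per group
  hits_ctrl <- 0L; hits_trt <- 0L
  reps <- 40
  for (s in seq_len(reps)) {
    sim <- gen_claims_cohort(
      n_patients = 40,
      assignment_coefs = c(intercept = 0),  # ~half treated
      shifts = list(ldl = c(control = 11, treated = 0)),
      baselines = c(ldl = 119), noise_sd = 15, seed = 500 + s)
    eff <- pre_post_effect(sim$patients, sim$labs, "ldl")
    g <- eff$groups
    if (g$paired_p[g$group == "control"] < 0.05) hits_ctrl <- hits_ctrl + 1L
    if (g$paired_p[g$group == "treated"] > 0.05) hits_trt <- hits_trt + 1L
  }
  expect_gt(hits_ctrl / reps, 0.5)
  expect_gt(hits_trt / reps, 0.5)
})

test_that("patient and lab tables round-trip through CSV", {
  sim <- gen_claims_cohort(n_patients = 30, seed = 38)
  pp <- withr::local_tempfile(fileext = ".csv")
  pl <- withr::local_tempfile(fileext = ".csv")
  write_patients(sim$patients, pp)
  write_labs(sim$labs, pl)
  pat <- read_patients(pp)
  labs <- read_labs(pl)
  expect_equal(pat$patient_id, sim$patients$patient_id)
  expect_equal(pat$treated, sim$patients$treated)
  expect_equal(labs$value, sim$labs$value, tolerance = 1e-10)
})
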