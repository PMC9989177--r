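---
title: "Screening spontaneous reports, claims and EHR data for mitigating drug pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening spontaneous reports, claims and EHR data for mitigating drug pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitiscreen)
```

## The problem

Atypical antipsychotics such as olanzapine are first-line treatments in
schizophrenia but disturb lipid homeostasis: LDL cholesterol and
triglycerides rise, HDL falls.  A reverse-translational repurposing
strategy looks for a co-prescribed drug that mitigates this adverse
effect, by combining three observational sources — spontaneous adverse
event reports (no denominators, no time stamps, but enormous scale),
insurance-claims laboratory data (annual, with prescription dates) and
electronic health records (daily resolution, smaller cohorts) — before
any wet-lab validation.  `mitiscreen` implements that desk arm as
reusable, tested modules with seeded synthetic generators standing in
for the proprietary databases.

## Disproportionality model

Spontaneous reports are cross-classified per drug into the 2×2 table
(a, b, c, d) of event-by-exposure.  The reporting odds ratio
ROR = (a/b)/(c/d) measures how over-represented the event is among
reports mentioning the drug; it is a reporting-bias-laden signal
statistic, not an incidence estimate.  Its Wald form,

* SE = sqrt(1/a + 1/b + 1/c + 1/d),
* 95% CI = exp(ln ROR ± 1.96·SE),
* Z = ln(ROR)/SE,

is used throughout because the Z-score compactly ranks thousands of
drugs where p-values would saturate.  When any cell is zero, 0.5 is
added to all four cells (Haldane–Anscombe); this keeps the ROR finite
and is the standard pharmacovigilance convention.  The arm-swap
antisymmetry (ROR → 1/ROR, Z → −Z) and the exact equivalence
|Z| > 1.96 ⇔ CI excludes 1 are enforced by property tests.

The mitigation screen is the same statistic computed *within* the
index-drug cohort, one table per co-reported drug.  Two selection rules
are emitted side by side: the `mitigator` flag (CI entirely below 1) and
the |Z| ranking, because a co-drug with a moderate ROR but many exposed
reports can out-rank a rarer co-drug with a lower point estimate.

Reports are deduplicated to one row per case (maximal version stamp,
ties broken by the smallest report identifier) before any counting, and
drug names pass through a many-to-one generic-name map; unmapped names
are retained verbatim with a warning rather than silently dropped, since
dropping them would shrink the *d* cell of every other drug.

Default screen floors are 100 exposed reports for the all-drugs screen
and 10 for the within-cohort screen; both are configurable.  Below these
counts the Wald interval is too wide to rank usefully and the continuity
correction dominates the estimate.

## Claims cohort: matching and pre/post effects

Treatment here means *preceding* co-medication (the co-drug started
before the index drug), so confounding by indication is the central
threat — in practice the co-drug of interest is prescribed
predominantly to elderly women.  The module:

1. fits a logistic propensity model of the treated flag on the
   configured covariates (IRLS via `stats::glm.fit`, deviance tolerance
   1e-8, at most 100 iterations; complete separation is detected from
   degenerate fitted probabilities, warned about, and coefficients are
   capped at ±15 so downstream matching still works);
2. matches treated to control 1:1 without replacement, processing
   treated units in descending score order with patient-id tie-breaks —
   the order is not identifiable from published summaries, so a fixed
   deterministic order was chosen for reproducibility.  No caliper is
   applied by default; one can be supplied;
3. summarizes balance per covariate (Welch t for continuous, Fisher
   exact for binary, standardized mean differences for all);
4. selects per patient the lab nearest before the index date (the index
   day itself counts as pre) and the earliest lab after it, both within
   12-month windows, averaging same-day duplicates, and tests the
   within-group change by paired t plus the between-group change-score
   difference by Welch t.

Patients missing any model covariate are excluded from scoring, and the
pre-window is half-open at the index date: a measurement exactly on the
index date is pre-treatment information.

## EHR trajectories

With daily-resolution records the outcome becomes a trajectory:
baseline (nearest test at or before first prescription, within 12
months) and quarterly checkpoints at months 3, 6, 9, 12.  Each
checkpoint takes the *latest* measurement in its half-open quarterly
window — the reading furthest from the index inside the quarter, the
only interpretation consistent with non-overlapping checkpoints.  A
month is 30.4375 days by default (configurable).  Missing checkpoints
are imputed by last observation carried forward; imputed values enter
both the paired month-vs-baseline tests and the between-group Welch
tests, consistent with LOCF semantics.  Patients without a baseline for
an analyte are excluded for that analyte, which is why per-analyte group
sizes differ.  Mixed-effects repeated-measures modelling is deliberately
out of scope; the per-checkpoint tests are the implemented surface.

## Expression follow-up

The cell-culture follow-up contrasts vehicle, the index drug alone and
the index drug plus each candidate metabolite, restricted to a
cholesterol-biosynthesis gene set.  The module works from gene-level
counts and effective lengths: TPM normalization, case-sensitive gene-set
restriction, removal of genes with mean vehicle TPM strictly below 1,
then a two-library Poisson test on pooled counts.

The test conditions on one library's count x and evaluates the
Audic–Claverie distribution
P(y | x) = t^y (x+y)! / (x! y! (1+t)^(x+y+1)), t = n2/n1, doubling the
smaller tail and capping at 1.  Because the conditioning choice is
arbitrary and the doubled-tail value is not symmetric in (x, y) — even
with equal library sizes the point mass makes the two orientations
differ — the reported p-value is defined as the **minimum over the two
conditionings**.  This makes symmetry p(x, y, n1, n2) = p(y, x, n2, n1)
exact by construction, leaves the equal-size reference values unchanged,
and keeps the empirical null rejection rate at the 5% level inside
[0.03, 0.07] in seeded simulations.  All tail sums run in log space with
the upper tail accumulated term-by-term until negligible, so p-values
far below double precision's addition limit retain full relative
accuracy (verified against direct factorial enumeration for all
x + y ≤ 50).

Replicates are pooled by summation before testing — the test models
replicate-free libraries, and pooling keeps the test consistent with
that model — while fold-changes use mean TPM with a 0.5-TPM pseudocount
(fold-change only, never the test).  A gene is called at |log2 FC| ≥ 1
and BH FDR ≤ 0.05, two-sidedly, with the FDR computed within the
post-filter gene set actually tested.

## Synthetic generators and what they do (not) show

Every generator is a pure function of its arguments plus a mandatory
seed (sub-stream seeds are derived deterministically), and attaches a
truth record sufficient to score recovery without re-reading the
configuration.

* `gen_reports()` draws independent drug exposures and multiplies the
  event odds by the planted index factor (default 8) and, within the
  index cohort, by the planted mitigation factor (default 0.5);
  duplicates are injected as earlier versions of existing cases.
* `gen_claims_cohort()` draws covariates at magnitudes typical of a
  lipid cohort (binary prevalences; truncated Gaussians, e.g. HbA1c
  floored at 3%), assigns treatment from a known logistic model, and
  plants group-specific post-index shifts — by default +11 mg/dL LDL
  and −5 mg/dL HDL in the unsupplemented group, 0 and +4 in the
  co-treated group, with 15 mg/dL measurement noise.
* `gen_ehr_series()` plants a linear drift per group (default +4.5
  mg/dL per month, i.e. +54 at month 12, versus flat) with scheduled
  quarterly visits dated at each checkpoint minus up to 14 days of
  jitter, a 0.8 default visit probability and missing-completely-at-
  random gaps.
* `gen_counts()` draws log-normal expression weights and Poisson (or
  negative-binomial when overdispersion is requested) counts, with a
  planted fold-change (default 4) on a random gene subset in random
  directions.

These generators emulate the *statistical structure* each stage assumes:
planted odds multipliers, a known assignment model, linear drift,
Poisson sampling.  They do not emulate reporting fashions or stimulated
reporting in spontaneous data, coding drift in claims, informative
(non-random) visit schedules or dropout in EHRs, or the correlated,
overdispersed structure of real transcriptomes.  Passing recovery tests
therefore demonstrates correctness of the estimators under their stated
models, not robustness to those real-world pathologies.

Problem sizes used by the test suite were chosen to make the planted
effects comfortably identifiable at desk scale: 100,000 reports for the
all-drugs screen (50,000 for the nested screen), cohorts of 1,000-5,000
patients, 400 + 23 EHR series matching the triglyceride arm sizes, and
5,000-gene matrices at one-million-read library sizes.  The sparse-visit
EHR setting demonstrates LOCF's attenuation of end-of-year drift; the
dense-visit setting is used when checking recovery of the planted
month-12 magnitude itself.

## Numerical and degenerate-input conventions

* All-zero 2×2 tables and empty exposure arms are errors, not NaNs.
* Both-groups-constant inputs: equal means give p = 1 by convention;
  unequal means with zero variance are an error (`welch_t`,
  `paired_t`).
* Benjamini–Hochberg q-values are order-aligned with their input and
  permutation-equivariant.
* Greedy matching and both screens are deterministic given their
  inputs; screens sort by |Z| with label tie-breaks so input order
  never matters.
* Laboratory window boundaries are half-open; the index day belongs to
  the pre-period.

## Known limitations

* The ROR quantifies reporting disproportionality; without denominators
  it cannot estimate incidence, and the mitigation screen inherits every
  reporting bias of the source database.
* Greedy matching is order-dependent by nature; optimal (minimum total
  distance) matching is not implemented.
* The two-library Poisson test treats pooled replicates as one library
  and therefore ignores biological variance; with true replicates a
  negative-binomial framework would be more appropriate.
* LOCF biases trajectories toward earlier values under monotone
  worsening; it is implemented because it is the field's convention for
  this design, not because it is optimal.
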