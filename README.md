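# mitiscreen

Reverse-translational drug repurposing asks a clinical question backwards:
given a drug that causes an adverse effect, which *other* drug, already on
the market and co-prescribed in the real world, mitigates it?  `mitiscreen`
implements the full desk-analysis arm of that strategy for
pharmacoepidemiologists and biostatisticians, using olanzapine-induced
dyslipidemia as its motivating case:

1. **Spontaneous-report screening** — deduplication, drug-name
   normalization and event flagging of FAERS-style report tables, an
   all-drugs disproportionality screen, and a nested *concomitant-drug
   mitigation screen* restricted to reports exposed to an index drug.
2. **Claims-cohort analysis** — propensity-score estimation by logistic
   regression, greedy 1:1 nearest-neighbour matching without replacement,
   baseline balance tables, and paired pre/post effect estimation for
   lipid outcomes around a first-prescription index date.
3. **EHR trajectories** — quarterly checkpoint extraction over the first
   year of exposure, last-observation-carried-forward imputation, and
   per-checkpoint within/between-group tests.
4. **Expression follow-up** — TPM normalization, gene-set restriction,
   low-expression filtering and two-library Poisson differential
   expression with Benjamini–Hochberg FDR control.
5. **Synthetic data** — seeded generators for all four input families
   with planted ground truth, so every stage is testable end to end
   without access to proprietary databases.

## The core statistic

For a drug *D* and an adverse event *E*, spontaneous reports are
cross-classified into a 2×2 table — *a* (E ∧ D), *b* (¬E ∧ D), *c*
(E ∧ ¬D), *d* (¬E ∧ ¬D) — and the reporting odds ratio is

    ROR = (a/b) / (c/d),   SE = sqrt(1/a + 1/b + 1/c + 1/d)
    95% CI = exp(ln ROR ± 1.96·SE),   Z = ln(ROR) / SE

Zero cells receive the Haldane–Anscombe correction (0.5 added to all four
cells).  The mitigation screen recomputes the same statistic for every
co-reported drug *within* the index-drug cohort; a co-drug whose CI lies
entirely below 1 is flagged as a candidate mitigator.

## Worked example

```r
library(mitiscreen)

# a synthetic corpus with a planted 8-fold event-odds elevation for the
# index drug and a planted 0.5x mitigation for a co-drug
reps <- gen_reports(n_reports = 100000, index_or = 8,
                    mitigation_or = 0.5, seed = 7)
reps <- deduplicate_reports(reps)
terms <- c("dyslipidaemia", "blood cholesterol increased",
           "hyperlipidaemia", "blood triglycerides increased",
           "low density lipoprotein increased",
           "high density lipoprotein decreased")

screen <- drug_event_screen(reps, terms, min_exposed = 100)
head(screen[, c("label", "a", "n_exposed", "ror", "ci_low", "ci_high", "z")], 3)
#>        label   a n_exposed       ror    ci_low   ci_high         z
#> 1 olanzapine 586      8146 7.6868270 6.9118029 8.5487550 37.612474
#> 2    aspirin 210     17942 0.7397522 0.6388001 0.8566581 -4.026697
#> 3 omeprazole 173     15075 0.7296762 0.6221844 0.8557389 -3.875967
```

The planted index drug tops the |Z| ranking and its CI covers the true
odds multiplier 8 (the mitigating co-drug drags the marginal estimate
slightly below it).  The nested screen then looks *inside* the
olanzapine cohort:

```r
cox <- concomitant_screen(reps, "olanzapine", terms, min_exposed = 10)
cox[cox$mitigator, c("label", "ror", "ci_low", "ci_high", "z")]
#>       label       ror    ci_low   ci_high         z
#> 1 vitamin d 0.3656499 0.1616891 0.8268945 -2.416515
```

The co-drug's ROR estimate covers the planted 0.5 and is flagged because
its interval excludes 1 — the pattern a mitigating co-prescription leaves
in spontaneous reports.

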