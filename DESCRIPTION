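Package: mitiscreen
Title: Adverse-Event Disproportionality Screening with Drug-Pair
    Mitigation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reverse-translational drug-repurposing analysis toolkit:
    reporting odds ratio disproportionality screening of spontaneous
    adverse-event reports with a nested concomitant-drug mitigation
    screen, propensity-score matched pre/post claims analysis,
    quarterly-checkpoint laboratory trajectories with last observation
    carried forward imputation, two-library Poisson differential
    expression with Benjamini-Hochberg false-discovery control, and
    seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
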