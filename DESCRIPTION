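Package: preopcard
Title: Preoperative Cardiac Risk Algorithm and Matched-Cohort Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a deterministic preoperative cardiac risk assessment
    algorithm (RCRI gate, Gupta MICA style logistic risk, functional capacity
    and surgical risk levels) that classifies each surgical patient to a single
    algorithm end point with an auditable decision trace, together with the
    retrospective cohort machinery needed to evaluate such an algorithm:
    eligibility and duplicate exclusions, 60-day preoperative service linkage,
    30-day MACE composite outcomes, propensity-score estimation and 1:1 greedy
    caliper matching with balance diagnostics, contingency and Mann-Whitney
    comparisons, and E-value sensitivity analysis for unmeasured confounding.
    A seeded synthetic cohort generator reproduces the marginal structure of a
    two-period (pre/post intervention) preoperative clinic population so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
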