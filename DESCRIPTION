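Package: handscreen
Title: Scoring and Diagnostic-Accuracy Evaluation of a Brief Nurse-Administered
    Screen for HIV-Associated Neurocognitive Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a brief screening battery for HIV-associated
    neurocognitive disorders (HAND): normative z-scoring of seven
    neuropsychological tests (Trail Making A/B, Digit Symbol, wordlist
    learning and recall, Grooved Pegboard both hands), a four-domain
    pathology rule (a domain is impaired if any constituent test falls
    below a z cutoff; the screen is positive with impairment in two or
    more domains), Likert questionnaire scoring for subjective cognitive
    complaints and depressive symptoms, and a combined screen-or-complaint
    criterion. Screen decisions are evaluated against a reference-standard
    diagnosis via 2x2 tables, sensitivity/specificity/predictive values
    with exact Clopper-Pearson confidence intervals, complaint-stratified
    analyses, and descriptive group comparisons. Includes a synthetic
    cohort simulator with a closed-form operating-characteristics oracle
    and a deterministic 30-patient synthetic cohort reconstructed from
    published marginal counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
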