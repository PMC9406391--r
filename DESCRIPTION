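Package: oncocausal
Title: Causal Transportability Checks and Milestone Treatment-Effect
    Calculation for Individualized Oncology Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for making individualized adjuvant-therapy decisions from
    randomized-trial summaries and prognostic nomogram output. Implements
    causal diagrams with selection nodes (d-separation, do-operator surgery,
    back-door analysis, do-calculus rule checks, S-admissibility and
    minimal adjustment-set search), an exponential-survival milestone
    treatment-effect calculator (hazards from milestone probabilities,
    hazard-ratio scaling, absolute risk reduction, sensitivity grids), a
    potential-outcomes cohort simulator with inverse probability of
    treatment weighting estimators, and an end-to-end clinical scenario
    evaluator for renal cell carcinoma adjuvant immunotherapy decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
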