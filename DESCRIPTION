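Package: adrtrigger
Title: Trigger-Tool Screening and Evaluation of Adverse Drug Reactions in
    Hospitalised Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the explicated adverse drug reaction (ADR) trigger
    tool of the Dutch geriatric polypharmacy guideline as a reusable
    screening-and-evaluation pipeline. Detects trigger-drug combinations in
    structured admission records via ATC-coded drug classes, adjudicates
    causality with the WHO-UMC scheme under a dual-rater consensus protocol
    with Cohen's kappa agreement, classifies recognition of ADRs by usual
    care, and computes per-trigger and overall positive predictive values,
    causality distributions, recognition rates and drug-class attribution.
    Ships a synthetic-cohort generator that emulates an acutely admitted
    geriatric polypharmacy population so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
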