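Package: trialdeid
Title: De-Identification of Patient-Level Clinical Trial Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing patient-level clinical trial datasets for
    sharing with third-party researchers. Implements a HIPAA Safe Harbor
    oriented workflow: a registry of the eighteen direct identifier classes,
    declaration-driven variable classification with a pattern scanner for
    identifier-like values in free text, consistent randomised re-coding of
    subject and site identifiers with code-key lifecycle management,
    replacement of dates by study days or per-subject offset dates and of
    date of birth by age, value generalisation (age top-coding and binning,
    race category mapping, rare-category pooling, ZIP truncation), verbatim
    free-text scrubbing, k-anonymity style residual-risk assessment over
    declared quasi-identifiers, and an auditable transformation report with
    an adversarial quality-control step. Includes a synthetic multi-domain
    trial generator with a ground-truth manifest so every rule is testable
    without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
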