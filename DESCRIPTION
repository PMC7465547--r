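Package: crctriage
Title: Rule-Based Referral Triage for Suspected Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes the Cancer Care Ontario referral-urgency criteria for
    patients with suspected colorectal cancer as a total, deterministic
    triage engine over tri-state clinical findings (present/absent/unknown),
    with configurable missing-data policies for the perianal-symptom
    sensitivity analysis. Includes cohort evaluation statistics (sensitivity
    with Wilson score and Clopper-Pearson confidence intervals, Cohen's
    kappa rater agreement, policy-comparison demotion ledger), a
    deterministic validation-cohort builder constrained to published
    per-priority criterion marginals, a seeded random cohort generator,
    CSV cohort input/output, report rendering, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
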