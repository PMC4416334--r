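Package: vacause
Title: Expert-Algorithm and Physician-Coded Verbal Autopsy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning causes of neonatal (0-27 days) and child
    (1-59 months) death from verbal autopsy interviews. Implements a
    declarative expert-algorithm rule engine with hierarchical primary-cause
    selection and co-morbidity detection, extraction of underlying, direct
    and contributing causes from physician death certificates,
    survey-weighted cause-specific mortality fractions with design-effect
    adjusted confidence intervals, two-proportion chi-square and Cohen's
    kappa agreement statistics, internal plausibility analyses (maternal
    infection versus early-onset neonatal infection; regional meningitis
    ecological comparison), and a synthetic cohort generator with known
    truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
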