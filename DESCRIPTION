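Package: mnmaudit
Title: Criterion-Based Audit of Maternal Near-Miss Cases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for criterion-based clinical audit of severe maternal
    outcomes. Encodes the WHO maternal near-miss identification criteria and
    their low-resource (Haydom) adaptation as an executable rule system,
    classifies case-level records into maternal deaths, near misses and
    non-cases, computes cohort indicators (severe maternal outcome ratio,
    case fatality rate, per-criterion frequencies, data completeness),
    assesses diagnostic validity of any criteria profile against maternal
    death with binomial confidence intervals, sweeps the blood-transfusion
    inclusion threshold, and ranks criteria by independent contribution via
    a greedy stepwise elimination. Includes deterministic reference fixtures
    reconstructed from published audit tables and a synthetic cohort
    generator with latent-severity co-occurrence and realistic missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
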