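Package: pedsignal
Title: Pediatric Pharmacovigilance Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end disproportionality-analysis pipeline for spontaneous
    adverse-event reporting data in the FAERS quarterly ASCII dialect: quarterly
    file ingestion with schema-drift tolerance, case-level deduplication by
    CASEID/FDA_DT/PRIMARYID, drug-of-interest cohort construction with age
    stratification, descriptive cohort summaries, four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    chi-squared, Bayesian confidence propagation neural network information
    component, and a gamma-Poisson-shrinker empirical Bayes geometric mean)
    combined through an all-four positivity gate at MedDRA preferred-term and
    system-organ-class level, and a pediatric-versus-adult reporting comparison
    via a comparison odds ratio and Fisher's exact test. A seeded synthetic
    FAERS-like data generator with known injected drug-event odds ratios
    supports parameter-recovery validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
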