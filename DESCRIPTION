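Package: pvsignal
Title: Pharmacovigilance Signal Detection for Drug-Associated Miscarriage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining spontaneous adverse-event reporting data for
    drug-associated miscarriage signals. Reads FAERS-style quarterly ASCII
    extracts, applies case-version deduplication and cohort selection rules,
    computes four disproportionality statistics (ROR, PRR, BCPNN information
    component, and the MGPS empirical-Bayes gamma-Poisson shrinker) with a
    multi-method consensus rule and Benjamini-Hochberg false-discovery-rate
    control, stratifies signals by age and body weight, models time-to-onset
    with a Weibull distribution and classifies hazard shape, fits a
    cross-validated gradient-boosted report-level risk model with SHAP-based
    feature importance, and annotates indication confounding. A synthetic
    report generator with known ground truth supports end-to-end validation
    without access to the full FAERS archive.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
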