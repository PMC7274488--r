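Package: thyromr
Title: Mendelian Randomization of Adiposity Traits on Thyroid Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for estimating causal effects of adiposity
    traits and type 2 diabetes liability on benign nodular thyroid disease
    and differentiated thyroid cancer. Provides a synthetic-cohort and
    summary-statistics generator with confounding and optional horizontal
    pleiotropy, an auditable ICD-10 registry phenotyping rule engine,
    weighted genetic risk score construction with instrument-strength
    checks, covariate-adjusted observational logistic associations,
    two-stage one-sample Mendelian randomization with sandwich standard
    errors and a genetic-liability quartile analysis, and two-sample
    summary-statistic estimators (inverse-variance weighted, MR-Egger,
    weighted median, penalized weighted median) with harmonization and
    pleiotropy diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor
Config/testthat/edition: 3
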