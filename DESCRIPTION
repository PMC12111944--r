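Package: hepindex
Title: Non-Invasive Indices for Hepatic Steatosis and Fibrosis in MASLD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the metabolic and hepatic non-invasive indices used to
    assess steatotic liver disease (triglyceride-glucose index, visceral
    adiposity index, lipid accumulation product, NAFLD fibrosis score and
    FIB-4), grades steatosis from controlled attenuation parameter (CAP)
    readings and stages fibrosis from transient elastography, derives
    ROC-based optimal, rule-in and rule-out cut-offs, and applies a two-stage
    sequential classifier that resolves part of the NFS/FIB-4 grey zone using
    TyG and VAI thresholds. Includes a seeded Gaussian-copula synthetic cohort
    generator calibrated to published marginal distributions and rank
    correlations so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
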