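Package: apneaflow
Title: Explainable Convolutional Estimation of the Pediatric Apnea-Hypopnea
    Index from Single-Channel Airflow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates pediatric obstructive sleep apnea severity from a
    single overnight airflow channel. A one-dimensional convolutional
    network regresses the number of apneic and hypopneic events in
    fixed-length z-scored airflow segments; per-segment estimates are
    averaged per subject and mapped to an apnea-hypopnea index (AHI)
    through a linear correction that absorbs the discrepancy between
    total sleep time and total recording time. The package bundles a
    pediatric airflow simulator with annotated ground-truth events,
    agreement and diagnostic statistics (intraclass correlation,
    Cohen's kappa, Bland-Altman limits, likelihood ratios), two
    attribution methods for the fitted network (multi-layer aggregated
    Grad-CAM and Deep-SHAP with a completeness guarantee), and a
    screening protocol that quantifies the achievable reduction in full
    polysomnography referrals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
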