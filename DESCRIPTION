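Package: rollrisk
Title: Self-Refreshing Disease-Risk Prediction from Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("rollrisk", "maintainers", email = "maintainers@rollrisk.org", role = c("aut", "cre"))
Description: An autonomous, monthly self-refreshing disease-risk prediction
    pipeline for event-level clinical tabular data (EHR- or claims-like).
    Builds patient-month time series with outcome censoring, screens a
    high-dimensional binary predictor space with two empirical retention
    criteria (an exact Fisher screen and a cumulative-binomial
    generalizability check), encodes retained predictors with
    past-and-present, historical and contemporaneous schemas, trains a
    shallow L2-regularized feed-forward network with a two-phase
    batch-size/early-stopping protocol, and evaluates monthly
    pseudo-prospective validation cohorts with AUROC, AUPRC, rank-band
    PPV/odds-ratio and threshold metrics. Ships a synthetic longitudinal
    EHR generator with planted risk and protective factors so every stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
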