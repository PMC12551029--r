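Package: dyadrisk
Title: Dual-Risk Epigenetic Indices and Dyadic Two-Wave Change Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes three DNA methylation derived risk indices from
    beta-value matrices - an EWAS-weighted epigenetic inflammation score
    (EIS), a four-locus alcohol T-score (ATS) with an elevated-consumption
    cutoff, and a six-CpG cardiac risk index (CRI) - and analyses their
    two-wave dynamics in couple-clustered cohorts. Estimation uses
    full-information maximum likelihood for the partially observed
    multivariate normal (EM), regression derived from the fitted moments,
    couple-cluster-robust sandwich standard errors, and chi-square based fit
    indices. A calibrated synthetic dyadic cohort generator (with
    missing-at-random participation patterns and optional CpG-level beta
    embedding) supports end-to-end pipeline runs and parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), sandwich, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
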