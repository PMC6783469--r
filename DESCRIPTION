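Package: spectriage
Title: Serum ATR-FTIR Spectral Triage: Simulation, Preprocessing and
    Resampled Diagnostic Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-level diagnostic classification of serum
    attenuated total reflection Fourier-transform infrared (ATR-FTIR)
    spectra, built around a brain-cancer triage protocol: a hierarchical
    synthetic-cohort generator (Gaussian band model with class effects,
    patient/well/replicate variance components, baseline drift and an
    optional silicon lattice band), spectral input/output (wide CSV and a
    JCAMP-DX subset), background quality control and a fixed
    crop/baseline/normalise/bin preprocessing chain, Kappa-tuned
    support-vector classification with per-patient consensus voting and a
    patient-disjoint 70/30 x 51-iteration resampling harness, blind
    external-cohort prediction, diagnostic metrics (sensitivity,
    specificity, Cohen's kappa, rank-based AUC), and precision-based
    sample-size utilities for prospective diagnostic-accuracy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
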