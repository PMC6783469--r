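#!/usr/bin/env Rscript

# Step 2: background QC and spectral preprocessing.
#
# Reads the simulated cohort from results/data/, checks every slide
# background against an acceptance range (quiet-window RMS and maximum
# absorbance), then runs each sample spectrum through the fixed chain
# crop (1800-1000 cm-1) -> rubber-band baseline -> L2 vector
# normalisation -> mean binning by 4, giving 200 features per spectrum.

suppressPackageStartupMessages(library(spectriage))

spectra <- read_wide_csv("results/data/cohort_spectra.csv")
manifest <- load_manifest("results/data/cohort_manifest.csv")
print(spectra)

config <- preprocess_config(
  qc = list(qc_rule("rms_noise_2200_2000", max = 0.1),
            qc_rule("max_absorbance", max = 2))
)
features <- preprocess_collection(spectra, config)

verdicts <- attr(features, "qc_verdicts")
cat("Background QC:", sum(vapply(verdicts, `[[`, logical(1), "pass")),
    "of", length(verdicts), "slides pass\n")
stopifnot(length(attr(features, "patients_without_spectra")) == 0)

cat("Feature table:", nrow(features), "spectra x",
    length(attr(features, "feature_cols")), "features\n")

utils::write.csv(features, "results/data/features.csv", row.names = FALSE)
cat("Wrote results/data/features.csv\n")
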