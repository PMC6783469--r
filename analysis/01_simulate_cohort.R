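#!/usr/bin/env Rscript

# Step 1: generate a synthetic serum ATR-FTIR cohort.
#
# There is no deposited patient data behind the triage protocol, so the
# workflow runs on a simulated stand-in: 30 cancer + 30 control patients,
# each contributing 9 spectra (3 wells x 3 acquisitions) plus a slide
# background, with the default band table (cancer perturbs amide II by
# x1.10 and the 1080 cm-1 band by x1.15), lognormal patient/well
# variance, polynomial baseline drift, a Si lattice feature and white
# noise. Outputs go to results/data/ as the package's wide-CSV
# interchange format plus a manifest.

suppressPackageStartupMessages(library(spectriage))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- simulation_config(seed = 2026)
design <- cohort_design(30, 30)

cat("Simulating", design$n_cancer + design$n_control, "patients at",
    config$n_wells_per_patient * config$n_spectra_per_well,
    "spectra each...\n")
sim <- simulate_cohort(config, design)
print(sim$spectra)

write_wide_csv(sim$spectra, file.path(out_dir, "cohort_spectra.csv"))
write_manifest(sim$manifest, file.path(out_dir, "cohort_manifest.csv"))

# one spectrum as JCAMP-DX, to demonstrate the interchange path
write_jcampdx(get_spectrum(sim$spectra, 1),
              file.path(out_dir, "example_spectrum.jdx"))

cat("ATR penetration depth at 1655 cm-1 (6.04 um), Si IRE, 45 deg:",
    round(penetration_depth(optics_params(1e4 / 1655, 3.42, 1.40, 45)), 3),
    "um\n")
cat("Wrote", file.path(out_dir, c("cohort_spectra.csv",
                                  "cohort_manifest.csv")), "\n")
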