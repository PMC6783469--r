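# Shared fixture builders. Everything is generated in code at test time.

# A noiseless one-band configuration: handy for closed-form checks.
one_band_config <- function(center = 1655, width = 25, amplitude = 1) {
  simulation_config(
    bands = list(band_spec(center, width, amplitude)),
    sigma_patient = 0, sigma_well = 0, sigma_noise = 0,
    baseline_scale = 0, si_band_amplitude = 0
  )
}

# A small simulated cohort shared by several tests (10 + 10 patients).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(seed = 101),
                                cohort_design(10, 10))
    }
    cache
  }
})

# A synthetic manifest with no spectra behind it, for harness-level tests.
toy_manifest <- function(n_cancer, n_control, cohort = "retrospective") {
  n <- n_cancer + n_control
  label <- rep(c("cancer", "non-cancer"), c(n_cancer, n_control))
  data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    cohort = cohort, label = label,
    tumour_type = ifelse(label == "cancer", "simulated tumour", ""),
    who_grade = "", age = 50, sex = "M",
    stringsAsFactors = FALSE
  )
}

# A minimal feature table (two dummy features, n_spectra rows/patient):
# enough structure for the resampling harness with a stub classifier.
make_stub_features <- function(manifest, n_spectra = 9) {
  wells <- rep(rep(c("1", "2", "3"), length.out = ceiling(n_spectra / 3)),
               each = min(3, n_spectra))[seq_len(n_spectra)]
  reps <- unlist(lapply(table(wells)[unique(wells)], seq_len),
                 use.names = FALSE)
  base <- data.frame(
    patient_id = rep(manifest$patient_id, each = n_spectra),
    well = rep(wells, nrow(manifest)),
    replicate = rep(reps, nrow(manifest)),
    stringsAsFactors = FALSE
  )
  base$wn1 <- 0
  base$wn2 <- 0
  class(base) <- c("feature_table", "data.frame")
  attr(base, "feature_cols") <- c("wn1", "wn2")
  base
}

# Independent sensitivity/specificity straight from label vectors.
oracle_sens_spec <- function(truth, pred) {
  list(
    sensitivity = sum(truth == "cancer" & pred == "cancer") /
      sum(truth == "cancer"),
    specificity = sum(truth == "non-cancer" & pred == "non-cancer") /
      sum(truth == "non-cancer")
  )
}

# Brute-force AUC: proportion of concordant positive/negative pairs,
# ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "cancer"]
  neg <- scores[labels == "non-cancer"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
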