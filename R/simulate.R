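#' One absorption band of the generative model
#'
#' A Gaussian band with a centre, width (Gaussian sigma), baseline
#' amplitude, and a multiplicative class effect applied for cancer
#' patients (1 means the band is unaffected by disease status).
#'
#' @param center Band centre in cm^-1.
#' @param width Gaussian sigma in cm^-1; must be positive.
#' @param base_amplitude Peak absorbance of the band; must be >= 0.
#' @param class_effect Multiplicative factor applied to the amplitude for
#'   cancer patients; must be positive.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center, width, base_amplitude, class_effect = 1) {
  if (width <= 0) stop("band_spec: 'width' must be positive", call. = FALSE)
  if (base_amplitude < 0) {
    stop("band_spec: 'base_amplitude' must be >= 0", call. = FALSE)
  }
  if (class_effect <= 0) {
    stop("band_spec: 'class_effect' must be positive", call. = FALSE)
  }
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude,
                 class_effect = class_effect),
            class = "band_spec")
}

#' Default serum band table
#'
#' Seven Gaussian bands mimicking the major features of a dried-serum
#' mid-IR spectrum: amide A (N-H stretch), CH3/CH2 stretches, amide I, II
#' and III, and the carbohydrate C-O region. The cancer class perturbs the
#' amide II band (x1.10) and the 1080 cm^-1 C-O band (x1.15), so the
#' amide I / amide II intensity ratio differs between classes.
#'
#' @param amide_ii_effect Class effect on the 1545 cm^-1 amide II band.
#' @param co_effect Class effect on the 1080 cm^-1 C-O band.
#' @return List of [band_spec()] objects.
#' @export
serum_band_table <- function(amide_ii_effect = 1.10, co_effect = 1.15) {
  list(
    band_spec(3300, 80, 0.50),                 # amide A
    band_spec(2960, 15, 0.15),                 # CH3 asym stretch
    band_spec(2873, 15, 0.10),                 # CH2 sym stretch
    band_spec(1655, 25, 1.00),                 # amide I
    band_spec(1545, 25, 0.70, amide_ii_effect), # amide II
    band_spec(1240, 30, 0.25),                 # amide III
    band_spec(1080, 30, 0.30, co_effect)       # C-O carbohydrates
  )
}

#' Configuration of the hierarchical spectrum simulator
#'
#' Collects everything the generator needs: the acquisition grid, the band
#' table, the variance components of the nested design (patient and well
#' effects are multiplicative lognormal; replicate noise is additive
#' Gaussian), a random polynomial baseline, an optional silicon lattice
#' band near 1100 cm^-1, and the replicate structure (3 wells x 3
#' acquisitions = 9 spectra per patient by default).
#'
#' @param acquisition An [acquisition_settings()] object.
#' @param bands List of [band_spec()] objects.
#' @param sigma_patient Lognormal scale of the per-patient amplitude
#'   multiplier (0 disables).
#' @param sigma_well Lognormal scale of the per-well multiplier.
#' @param sigma_noise Additive white-noise standard deviation (absorbance).
#' @param baseline_order Polynomial degree of the random baseline.
#' @param baseline_scale Standard deviation of the baseline coefficients
#'   (0 disables the baseline).
#' @param si_band_amplitude Absorbance of the broad Si lattice feature at
#'   1100 cm^-1 (0 disables it).
#' @param n_wells_per_patient Sample wells per patient (default 3).
#' @param n_spectra_per_well Replicate acquisitions per well (default 3).
#' @param seed Base integer seed; patient-level streams are derived from
#'   it deterministically.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(acquisition = acquisition_settings(),
                              bands = serum_band_table(),
                              sigma_patient = 0.10,
                              sigma_well = 0.05,
                              sigma_noise = 0.005,
                              baseline_order = 2,
                              baseline_scale = 0.01,
                              si_band_amplitude = 0.02,
                              n_wells_per_patient = 3,
                              n_spectra_per_well = 3,
                              seed = 1L) {
  for (fld in c("sigma_patient", "sigma_well", "sigma_noise",
                "baseline_scale", "si_band_amplitude")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("simulation_config: '", fld, "' must be a single number >= 0",
           call. = FALSE)
    }
  }
  if (n_wells_per_patient < 1 || n_spectra_per_well < 1) {
    stop("simulation_config: replicate counts must be >= 1", call. = FALSE)
  }
  if (baseline_order < 0) {
    stop("simulation_config: 'baseline_order' must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(acquisition, "acquisition_settings"))
  for (b in bands) stopifnot(inherits(b, "band_spec"))
  structure(
    list(acquisition = acquisition, bands = bands,
         sigma_patient = sigma_patient, sigma_well = sigma_well,
         sigma_noise = sigma_noise, baseline_order = baseline_order,
         baseline_scale = baseline_scale,
         si_band_amplitude = si_band_amplitude,
         n_wells_per_patient = as.integer(n_wells_per_patient),
         n_spectra_per_well = as.integer(n_spectra_per_well),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Cohort design for the simulator
#'
#' @param n_cancer Number of cancer patients.
#' @param n_control Number of control (non-cancer) patients.
#' @param tumour_type_counts Optional data.frame with columns
#'   `tumour_type`, `who_grade`, `count`; counts must sum to `n_cancer`.
#' @param age_range_cancer,age_range_control Two-element numeric ranges
#'   for deterministic age assignment.
#' @param cohort Cohort tag carried into the manifest.
#' @param allow_empty_class Permit zero patients in a class (off by
#'   default; an empty class is usually a design mistake).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_cancer, n_control, tumour_type_counts = NULL,
                          age_range_cancer = c(21, 96),
                          age_range_control = c(19, 69),
                          cohort = "retrospective",
                          allow_empty_class = FALSE) {
  if (n_cancer < 0 || n_control < 0) {
    stop("cohort_design: patient counts must be >= 0", call. = FALSE)
  }
  if (!allow_empty_class && (n_cancer == 0 || n_control == 0)) {
    stop("cohort_design: a class has zero patients; set allow_empty_class",
         " = TRUE if intentional", call. = FALSE)
  }
  if (!is.null(tumour_type_counts)) {
    stopifnot(all(c("tumour_type", "count") %in% names(tumour_type_counts)))
    if (sum(tumour_type_counts$count) != n_cancer) {
      stop("cohort_design: tumour_type_counts sum ",
           sum(tumour_type_counts$count), " != n_cancer ", n_cancer,
           call. = FALSE)
    }
  }
  structure(
    list(n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
         tumour_type_counts = tumour_type_counts,
         age_range_cancer = age_range_cancer,
         age_range_control = age_range_control,
         cohort = cohort),
    class = "cohort_design"
  )
}

# Deterministic per-patient stream seed derived from the base seed.
# Kept below 2^31 so set.seed() accepts it on 32-bit integer platforms.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 48271 + index * 1299709) %% 2147483629)
}

noiseless_signal <- function(config, label) {
  wn <- wavenumber_grid(config$acquisition)
  y <- numeric(length(wn))
  for (b in config$bands) {
    amp <- b$base_amplitude * if (label == "cancer") b$class_effect else 1
    y <- y + amp * exp(-(wn - b$center)^2 / (2 * b$width^2))
  }
  y
}

si_lattice_term <- function(config) {
  wn <- wavenumber_grid(config$acquisition)
  config$si_band_amplitude * exp(-(wn - 1100)^2 / (2 * 60^2))
}

random_baseline <- function(config) {
  wn <- wavenumber_grid(config$acquisition)
  if (config$baseline_scale == 0) return(numeric(length(wn)))
  # polynomial in x scaled to [-1, 1] so coefficients are comparable
  x <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
  coef <- stats::rnorm(config$baseline_order + 1, 0, config$baseline_scale)
  drop(outer(x, 0:config$baseline_order, `^`) %*% coef)
}

#' Simulate a single serum-like spectrum
#'
#' The generative model is a sum of Gaussian bands, each scaled by its
#' class effect (cancer only), a per-patient multiplier and a per-well
#' multiplier, plus a random polynomial baseline, a fixed Si lattice term
#' and additive white noise. Randomness (baseline and noise) is drawn from
#' the current RNG state; seed it for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param patient_label `"cancer"` or `"non-cancer"`.
#' @param patient_effect Per-patient multiplicative effect (> 0).
#' @param well_effect Per-well multiplicative effect (> 0).
#' @param patient_id,well,replicate Identity metadata for the output.
#' @param role `"sample"` or `"background"`; a background spectrum has no
#'   serum bands, only baseline, Si term and noise.
#' @return An [ftir_spectrum()] on the configured grid.
#' @export
simulate_spectrum <- function(config, patient_label = "non-cancer",
                              patient_effect = 1, well_effect = 1,
                              patient_id = "sim", well = "1",
                              replicate = 1L, role = "sample") {
  stopifnot(inherits(config, "simulation_config"))
  if (!patient_label %in% c("cancer", "non-cancer")) {
    stop("simulate_spectrum: 'patient_label' must be 'cancer' or 'non-cancer'",
         call. = FALSE)
  }
  if (patient_effect <= 0 || well_effect <= 0) {
    stop("simulate_spectrum: effect multipliers must be positive",
         call. = FALSE)
  }
  wn <- wavenumber_grid(config$acquisition)
  signal <- if (role == "sample") {
    noiseless_signal(config, patient_label) * patient_effect * well_effect
  } else {
    numeric(length(wn))
  }
  y <- signal + random_baseline(config) + si_lattice_term(config)
  if (config$sigma_noise > 0) {
    y <- y + stats::rnorm(length(wn), 0, config$sigma_noise)
  }
  ftir_spectrum(wn, y, patient_id = patient_id, well = well,
                replicate = replicate, role = role,
                acquisition = config$acquisition)
}

#' Simulate a full patient cohort
#'
#' Generates `n_wells_per_patient * n_spectra_per_well` sample spectra per
#' patient (default 9: triplicate wells, each acquired three times) plus
#' one background spectrum per patient slide, together with a cohort
#' manifest. Per-patient and per-well amplitude multipliers are lognormal;
#' every patient's random stream is derived deterministically from the
#' config seed and the patient index, so cohorts are reproducible and
#' individual patients are stable under cohort-size changes.
#'
#' @param config A [simulation_config()].
#' @param design A [cohort_design()].
#' @return List with elements `manifest` (data.frame: patient_id, cohort,
#'   label, tumour_type, who_grade, age, sex) and `spectra`
#'   (a [spectra_collection()]).
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 7),
#'                        cohort_design(5, 5))
#' nrow(sim$manifest)                  # 10 patients
#' sum(sim$spectra$meta$role == "sample") # 90 spectra
#' @export
simulate_cohort <- function(config, design) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(design, "cohort_design"))
  n_total <- design$n_cancer + design$n_control
  if (n_total == 0) stop("simulate_cohort: empty cohort", call. = FALSE)
  labels <- rep(c("cancer", "non-cancer"),
                c(design$n_cancer, design$n_control))
  ids <- sprintf("%s%04d",
                 ifelse(labels == "cancer", "C", "N"),
                 c(seq_len(design$n_cancer), seq_len(design$n_control)))
  tumour <- rep("", n_total)
  grade <- rep("", n_total)
  if (!is.null(design$tumour_type_counts)) {
    tt <- design$tumour_type_counts
    tumour[labels == "cancer"] <- rep(tt$tumour_type, tt$count)
    if ("who_grade" %in% names(tt)) {
      grade[labels == "cancer"] <- rep(tt$who_grade, tt$count)
    }
  } else {
    tumour[labels == "cancer"] <- "simulated tumour"
  }
  age <- numeric(n_total)
  for (cls in c("cancer", "non-cancer")) {
    rng <- if (cls == "cancer") design$age_range_cancer else
      design$age_range_control
    k <- sum(labels == cls)
    age[labels == cls] <- round(seq(rng[1], rng[2], length.out = max(k, 2)))[seq_len(k)]
  }
  sex <- rep(c("M", "F"), length.out = n_total)

  manifest <- data.frame(
    patient_id = ids, cohort = design$cohort, label = labels,
    tumour_type = tumour, who_grade = grade, age = age, sex = sex,
    stringsAsFactors = FALSE
  )

  spectra <- vector("list",
                    n_total * (config$n_wells_per_patient *
                                 config$n_spectra_per_well + 1))
  k <- 0L
  for (i in seq_len(n_total)) {
    set.seed(derive_seed(config$seed, i))
    pat_eff <- if (config$sigma_patient > 0) {
      stats::rlnorm(1, 0, config$sigma_patient)
    } else 1
    for (w in seq_len(config$n_wells_per_patient)) {
      well_eff <- if (config$sigma_well > 0) {
        stats::rlnorm(1, 0, config$sigma_well)
      } else 1
      for (r in seq_len(config$n_spectra_per_well)) {
        k <- k + 1L
        spectra[[k]] <- simulate_spectrum(
          config, labels[i], pat_eff, well_eff,
          patient_id = ids[i], well = as.character(w), replicate = r
        )
      }
    }
    k <- k + 1L
    spectra[[k]] <- simulate_spectrum(
      config, labels[i], 1, 1, patient_id = ids[i],
      well = "background", replicate = 1L, role = "background"
    )
  }
  list(manifest = manifest, spectra = spectra_collection(spectra))
}

#' Optical parameters of an ATR measurement
#'
#' @param wavelength Wavelength of the IR beam in micrometres.
#' @param n_ire Refractive index of the internal reflection element.
#' @param n_sample Refractive index of the sample.
#' @param angle Angle of incidence in degrees.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(wavelength, n_ire, n_sample, angle) {
  if (!(n_ire > n_sample && n_sample > 0)) {
    stop("optics_params: require n_ire > n_sample > 0", call. = FALSE)
  }
  if (wavelength <= 0) {
    stop("optics_params: 'wavelength' must be positive", call. = FALSE)
  }
  structure(list(wavelength = wavelength, n_ire = n_ire,
                 n_sample = n_sample, angle = angle),
            class = "optics_params")
}

#' Penetration depth of the evanescent wave
#'
#' Depth at which the evanescent field decays to 1/e of its interface
#' value: `lambda / (2 pi n1 sqrt(sin^2 theta - (n2/n1)^2))`. Valid only
#' under total internal reflection, i.e. `sin^2 theta > (n2/n1)^2`.
#'
#' @param p An [optics_params()] object.
#' @return Penetration depth in the same length unit as the wavelength
#'   (micrometres by convention).
#' @examples
#' # silicon IRE against dried serum at 45 degrees, 10 um (1000 cm-1)
#' penetration_depth(optics_params(10, 3.42, 1.40, 45))
#' @export
penetration_depth <- function(p) {
  stopifnot(inherits(p, "optics_params"))
  s2 <- sin(p$angle * pi / 180)^2
  ratio2 <- (p$n_sample / p$n_ire)^2
  if (s2 <= ratio2) {
    stop("penetration_depth: no total internal reflection at this angle",
         " (sin^2 theta <= (n2/n1)^2)", call. = FALSE)
  }
  p$wavelength / (2 * pi * p$n_ire * sqrt(s2 - ratio2))
}
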