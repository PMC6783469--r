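test_that("the generative model evaluates to its closed form", {
  # degenerate config: nothing switched on -> flat zero on the full grid
  cfg <- simulation_config(bands = list(), sigma_patient = 0,
                           sigma_well = 0, sigma_noise = 0,
                           baseline_scale = 0, si_band_amplitude = 0)
  s <- simulate_spectrum(cfg, "non-cancer")
  expect_length(s$absorbance, 3051)
  expect_equal(s$wavenumbers[1], 4000)
  expect_equal(s$wavenumbers[3051], 950)
  expect_true(all(s$absorbance == 0))

  # single Gaussian band: exact values at the centre and one sigma out
  s <- simulate_spectrum(one_band_config(), "non-cancer")
  expect_equal(s$absorbance[s$wavenumbers == 1655], 1.0)
  expect_equal(s$absorbance[s$wavenumbers == 1680], exp(-0.5))
  expect_equal(s$absorbance[s$wavenumbers == 1630], exp(-0.5))

  # class effect multiplies the affected band only (bands chosen far
  # enough apart that their Gaussian tails do not overlap numerically)
  cfg <- simulation_config(
    bands = list(band_spec(1655, 10, 1), band_spec(1100, 10, 0.7, 1.10)),
    sigma_patient = 0, sigma_well = 0, sigma_noise = 0,
    baseline_scale = 0, si_band_amplitude = 0)
  sc <- simulate_spectrum(cfg, "cancer")
  sn <- simulate_spectrum(cfg, "non-cancer")
  expect_equal(sc$absorbance[sc$wavenumbers == 1100],
               1.10 * sn$absorbance[sn$wavenumbers == 1100])
  expect_equal(sc$absorbance[sc$wavenumbers == 1655],
               sn$absorbance[sn$wavenumbers == 1655])
})

test_that("invalid simulator configuration is rejected by field name", {
  expect_error(band_spec(1655, -1, 1), "width")
  expect_error(band_spec(1655, 25, -0.1), "base_amplitude")
  expect_error(band_spec(1655, 25, 1, 0), "class_effect")
  expect_error(simulation_config(sigma_noise = -1), "sigma_noise")
  expect_error(acquisition_settings(950, 4000), "wavenumber_start")
  expect_error(acquisition_settings(resolution = 0.5), "resolution")
  expect_error(simulate_spectrum(one_band_config(), "cancer",
                                 patient_effect = 0), "multipliers")
})

test_that("simulated cohorts have the nested replicate structure", {
  sim <- small_cohort()
  expect_equal(nrow(sim$manifest), 20)
  expect_equal(sum(sim$spectra$meta$role == "sample"), 180)
  # 9 sample spectra per patient, always
  expect_true(all(spectra_per_patient(sim$spectra) == 9))
  # one background per slide
  expect_equal(sum(sim$spectra$meta$role == "background"), 20)
  # manifest labels match the generating class encoded in the id prefix
  expect_identical(sim$manifest$label,
                   ifelse(grepl("^C", sim$manifest$patient_id),
                          "cancer", "non-cancer"))
})

test_that("seeding is deterministic and seed changes move the data", {
  cfg <- simulation_config(seed = 5)
  d <- cohort_design(3, 3)
  a <- simulate_cohort(cfg, d)
  b <- simulate_cohort(cfg, d)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$manifest, b$manifest)
  c <- simulate_cohort(simulation_config(seed = 6), d)
  expect_identical(a$manifest, c$manifest) # structure is seed-free
  expect_false(identical(a$spectra$absorbance, c$spectra$absorbance))
})

test_that("zero variance components leave a class with identical spectra", {
  cfg <- simulation_config(sigma_patient = 0, sigma_well = 0,
                           sigma_noise = 0, baseline_scale = 0, seed = 9)
  sim <- simulate_cohort(cfg, cohort_design(3, 3))
  for (cls in c("cancer", "non-cancer")) {
    ids <- sim$manifest$patient_id[sim$manifest$label == cls]
    cols <- sim$spectra$meta$patient_id %in% ids &
      sim$spectra$meta$role == "sample"
    block <- sim$spectra$absorbance[, cols, drop = FALSE]
    expect_true(all(block == block[, 1]))
  }
})

test_that("replicate means converge to the noiseless model curve", {
  cfg <- simulation_config(bands = serum_band_table(), sigma_patient = 0,
                           sigma_well = 0, sigma_noise = 0.005,
                           baseline_scale = 0, si_band_amplitude = 0,
                           seed = 2)
  set.seed(2)
  n <- 200
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + simulate_spectrum(cfg, "non-cancer")$absorbance
  }
  noiseless <- simulate_spectrum(
    simulation_config(bands = serum_band_table(), sigma_patient = 0,
                      sigma_well = 0, sigma_noise = 0, baseline_scale = 0,
                      si_band_amplitude = 0), "non-cancer")$absorbance
  # pointwise error is N(0, sd/sqrt(n)); 5 sigma over 3051 points
  expect_lt(max(abs(acc / n - noiseless)), 5 * 0.005 / sqrt(n))
})

test_that("cohort design validates tumour mixes and empty classes", {
  expect_error(cohort_design(10, 0), "zero patients")
  expect_silent(cohort_design(10, 0, allow_empty_class = TRUE))
  tt <- data.frame(tumour_type = c("a", "b"), count = c(3, 4))
  expect_error(cohort_design(10, 5, tumour_type_counts = tt), "sum")
  sim <- simulate_cohort(simulation_config(seed = 1),
                         cohort_design(7, 5, tumour_type_counts = tt))
  expect_equal(sum(sim$manifest$tumour_type == "a"), 3)
  expect_equal(sum(sim$manifest$tumour_type == "b"), 4)
})

test_that("penetration depth follows the evanescent-wave formula", {
  # silicon vs diamond at 10 um, 45 degrees, serum-like sample
  expect_equal(penetration_depth(optics_params(10, 3.42, 1.40, 45)),
               0.8071, tolerance = 1e-3)
  d_dia <- penetration_depth(optics_params(10, 2.40, 1.40, 45))
  expect_equal(d_dia, 1.6593, tolerance = 1e-3)
  # silicon probes shallower than diamond
  expect_lt(penetration_depth(optics_params(10, 3.42, 1.40, 45)), d_dia)
  # exactly linear in wavelength
  expect_equal(penetration_depth(optics_params(20, 3.42, 1.40, 45)),
               2 * penetration_depth(optics_params(10, 3.42, 1.40, 45)))
  # strictly decreasing in IRE index and in angle over the valid domain
  n1 <- seq(2.4, 4.0, by = 0.2)
  d_n <- vapply(n1, function(n)
    penetration_depth(optics_params(10, n, 1.40, 45)), numeric(1))
  expect_true(all(diff(d_n) < 0))
  th <- seq(40, 85, by = 5)
  d_t <- vapply(th, function(a)
    penetration_depth(optics_params(10, 3.42, 1.40, a)), numeric(1))
  expect_true(all(diff(d_t) < 0))
  # below the critical angle there is no evanescent field
  expect_error(penetration_depth(optics_params(10, 1.5, 1.4, 45)),
               "total internal reflection")
  expect_error(optics_params(10, 1.4, 1.5, 45), "n_ire > n_sample")
})
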