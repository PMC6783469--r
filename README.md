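# spectriage

Patient-level diagnostic classification of serum ATR-FTIR spectra, built
around a brain-cancer triage protocol: spectra are acquired in
triplicate wells on disposable silicon internal-reflection-element
slides (nine spectra per patient), preprocessed per spectrum, classified
per spectrum by a Kappa-tuned RBF support-vector machine, and the
patient's diagnosis is the **consensus vote** of their spectra —
evaluated under a patient-disjoint 70/30 × 51-iteration resampling
protocol, with blind prediction of external cohorts and precision-based
sample-size planning for prospective validation.

The package is aimed at spectroscopists and biostatisticians working on
biofluid vibrational-spectroscopy diagnostics who need the *protocol* —
splitting hygiene, tuning criterion, voting, resampled metrics — as
tested, reusable code. Because no patient-level spectra from the
underlying studies were ever deposited, the package ships a hierarchical
synthetic-cohort generator (Gaussian band model with class effects on
the amide II and 1080 cm⁻¹ bands, lognormal patient/well variance,
baseline drift, Si lattice band, white noise) plus the published cohort
tables as built-in manifests, so every stage is testable end to end.

## The model in brief

A simulated sample spectrum is

    A(ν) = Σ_b a_b · c_b^[cancer] · P · W · exp(−(ν−μ_b)²/2σ_b²)
           + baseline(ν) + Si(ν) + ε(ν)

and the diagnostic pipeline is

    crop 1800–1000 cm⁻¹ → rubber-band baseline → L2 normalise → bin ×4
    → SVM tuned by per-spectrum Cohen's κ over patient-disjoint 5-fold CV
    → per-patient majority vote → sensitivity / specificity / AUC
      averaged over 51 patient-disjoint 70/30 splits

Cohen's κ = (p_o − p_e)/(1 − p_e); AUC is the Mann–Whitney concordance
probability (ties ½). Cancer is the positive class; consensus ties
(possible only after QC drops) resolve to cancer, the
triage-conservative direction.

## Worked example

```r
library(spectriage)

# simulate 20 patients (10 cancer / 10 control), 9 spectra each
sim <- simulate_cohort(simulation_config(seed = 101), cohort_design(10, 10))
features <- preprocess_collection(sim$spectra)

# 5 iterations of the 70/30 protocol with SVM tuning
res <- run_resampling(features, sim$manifest,
                      resampling_plan(n_iterations = 5, base_seed = 1))
print(res)
#> <resampling_summary> 5 iteration(s), 20 patients (10 cancer)
#>   mean sensitivity 1.000, specificity 1.000, AUC 1.000
```

At the default class effects the synthetic classes are cleanly
separable, so the protocol recovers every test patient: the point of
the run is the machinery (splits, folds, tuning, voting), which
`assert_no_leakage(res)` re-proves id-by-id.

The published interim validation cohort (104 patients, 12 cancers) is
packaged, and its printed percentages pin the confusion matrix
uniquely:

```r
tp <- counts_matching_percent(83.3, 12)   # -> 10
tn <- counts_matching_percent(87.0, 92)   # -> 80
cm <- confusion_matrix(tp = tp, fp = 92 - tn, tn = tn, fn = 12 - tp)
ss <- sens_spec(cm)
format_percent(ss$sensitivity); format_percent(ss$specificity)
#> [1] "83.3%"
#> [1] "87.0%"
```

Sample-size planning for a prospective study at 2 % prevalence:

```r
n_for_precision(design_params("specificity", 0.75, 0.05, 0.02))
#> <sample_size> 289 patients of the relevant class (98.0% of recruits) -> 295 total recruits
```

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
data and write tables and figures under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | simulate a 60-patient cohort; write wide-CSV spectra + manifest |
| `02_preprocess.R` | background QC; crop/baseline/normalise/bin to a feature table |
| `03_resampled_validation.R` | 11-iteration resampled SVM evaluation; metrics + report |
| `04_prospective_prediction.R` | blind ensemble prediction of an external cohort; published interim worked example |
| `05_study_design.R` | precision-based sample sizes; interim recalibration |

Run them in order from the repository root:
`Rscript analysis/01_simulate_cohort.R` and so on.

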