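---
title: "Serum ATR-FTIR triage: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum ATR-FTIR triage: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Attenuated total reflection FTIR spectroscopy of dried blood serum,
combined with a machine-learning classifier, can triage patients with
suspected brain cancer: a per-patient "cancer / non-cancer" call that
prioritises referral for definitive imaging. The measurement itself is
cheap — a drop of serum dried onto a silicon internal reflection
element (IRE), nine absorbance spectra per patient (three wells, three
acquisitions each, 4 cm^-1 resolution on a 1 cm^-1 grid) — but the
patient-level spectra behind the published studies were never
deposited. This package therefore implements the *protocol* end to end
and validates it on data from a hierarchical simulator whose structure
matches what the instrument produces, plus the published cohort tables,
which are packaged as manifests.

`spectriage` covers six stages: synthetic cohort generation, spectral
I/O, background QC and preprocessing, Kappa-tuned SVM classification
with patient-level consensus voting under a resampled validation
protocol, diagnostic metrics, and precision-based sample-size planning
for prospective validation.

# The synthetic cohort generator

The generator is first-class, tested code — it defines the conditions
under which every downstream claim is checked. A sample spectrum is

$$A(\nu) \;=\; \sum_b a_b\, c_b^{[\text{cancer}]}\, P\, W\,
  e^{-(\nu-\mu_b)^2/2\sigma_b^2} \;+\; \text{baseline}(\nu)
  \;+\; \text{Si}(\nu) \;+\; \varepsilon(\nu),$$

with Gaussian bands $b$ (centre $\mu_b$, width $\sigma_b$, amplitude
$a_b$), a multiplicative class effect $c_b$ applied only for cancer
patients, lognormal per-patient ($P$) and per-well ($W$) multipliers,
a random polynomial baseline, a fixed broad Gaussian at 1100 cm^-1 for
the Si lattice contribution, and additive white noise $\varepsilon$.

The default band table mimics dried serum: amide A (3300/σ80), CH3
(2960/15), CH2 (2873/15), amide I (1655/25, amplitude 1), amide II
(1545/25, amplitude 0.7), amide III (1240/30) and the carbohydrate C–O
region (1080/30). Disease enters as a 1.10 factor on amide II and 1.15
on the 1080 cm^-1 band, perturbing the amide I/II ratio that serum
studies repeatedly flag. These are modelling choices, not estimates
from any cohort: no generative model or variance decomposition was
ever published for this assay.

Default variance components, chosen once as plausible for replicate
serum ATR-FTIR measurements and kept fixed: patient effect lognormal
with scale 0.10 (≈10% biological amplitude variation), well effect
0.05 (deposition/drying variation), additive noise sd 0.005 absorbance
(consistent with a quiet-window RMS a spectrometer at 16 co-added
scans can reach), baseline degree 2 with coefficient sd 0.01, Si band
amplitude 0.02. Because the patient and well effects are *global*
multipliers, L2 normalisation removes them almost entirely; the class
signal survives as a band-ratio change. That is the intended behaviour
of the real pre-processing chain too.

Seeding: one base seed; each patient's stream is derived
deterministically from (seed, patient index), so cohorts are
reproducible and individual patients do not change when the cohort
grows.

```{r}
library(spectriage)
sim <- simulate_cohort(simulation_config(seed = 2026),
                       cohort_design(30, 30))
```

The generator also houses the one piece of ATR optics the analysis
needs: the evanescent-field penetration depth
$d_p = \lambda / (2\pi n_1 \sqrt{\sin^2\theta - (n_2/n_1)^2})$,
which quantifies how the move from diamond ($n_1 = 2.4$) to silicon
($n_1 = 3.42$) IREs shallows the probed layer
(`penetration_depth()`).

What the simulator does *not* emulate: coffee-ring drying spatial
heterogeneity, instrument line-shape/apodization, water-vapour and
CO2 interference, batch effects between slides, and any realistic
overlap between disease classes beyond the stated band effects.
Passing tests on this data therefore demonstrate that the *protocol*
is implemented correctly and recovers a signal of the assumed form —
they say nothing about clinical accuracy on real serum.

# Preprocessing

The chain is fixed, per spectrum, in this order:

1. **Crop** to the fingerprint region, 1800–1000 cm^-1 (801 points on
   the 1 cm^-1 grid).
2. **Rubber-band baseline**: subtract the lower convex hull of the
   trace. Parameter-free, idempotent, output non-negative with at
   least the two endpoints exactly zero. The published protocol calls
   its own pre-processing proprietary know-how; rubber-band is the
   field-standard parameter-free choice for serum ATR-FTIR.
3. **Vector (L2) normalisation** — after baseline correction, so
   offsets never dominate the norm. An amide-I peak normalisation is
   available as an alternative.
4. **Mean binning by 4**, matching the 4 cm^-1 optical resolution of a
   1 cm^-1-spaced grid. 801 points do not divide by 4; the final
   single point is truncated (800 → 200 features). This truncation
   rule is documented here and pinned by tests.

Preprocessing is strictly per-spectrum: no statistic is pooled across
spectra or patients, so the chain cannot leak information from test to
training patients no matter where it is applied.

Background QC is a separate, explicit gate (`qc_background()`):
acceptance intervals on quiet-window RMS noise (2200–2000 cm^-1),
integrated absorbance, and maximum absorbance, applied to the
background well of each slide. Verdicts record every metric value. A
patient left with zero passing spectra is flagged in the feature-table
attributes, never silently dropped.

# Classification protocol

The unit of diagnosis is the patient; the unit of classification is
the spectrum.

* **Split**: patients (never spectra) are split 70/30 into training
  and test portions, stratified by class; iteration $i$ of the
  resampling plan uses seed `base_seed + i`. On the packaged
  724-patient retrospective manifest this gives 341 + 166 = 507
  training and 217 test patients.
* **Tune**: an RBF-kernel SVM over the grid cost ∈ {0.1, 1, 10, 100} ×
  gamma ∈ {1e-3 … 10} (log steps), selecting the grid point with the
  highest mean per-spectrum Cohen's kappa across 5 cross-validation
  folds. Folds are *patient-disjoint* (kappa is still computed per
  spectrum): spectrum-level folds would place a patient's replicates
  on both sides of a fold boundary and overstate validation kappa.
  Ties resolve to the smallest cost, then the smallest gamma.
* **Consensus**: the tuned model labels each of a test patient's nine
  spectra independently; the patient's diagnosis is the majority
  vote. With nine spectra ties are impossible; after QC drops an even
  count can tie, and ties resolve to *cancer* — a triage tool should
  fail toward referral, since sensitivity carries the patient cost.
* **Iterate**: the whole procedure repeats 51 times (the package
  default) and metrics are reported as means and standard deviations
  over iterations. Per-patient ROC scores use the mean SVM decision
  margin over the patient's spectra (the published work reports AUC
  but not its patient-level score construction; the mean margin is the
  natural choice and is monotone-invariant for the rank-based AUC).
* **External prediction** (`predict_external()`): all retained
  iteration models vote on every spectrum of an external cohort and
  one consensus is taken per patient over all model × spectrum
  predictions; a single-model mode exists as an option. Blinding is
  enforced structurally — the prediction interface never receives
  labels, and any external patient id that appeared in any training
  fold raises an error. `assert_no_leakage()` re-proves the id
  hygiene of a finished run.

The SVM itself is standard machinery (libsvm via `e1071`); everything
around it — the kappa-maximising tuning criterion, the patient-level
hygiene, the consensus rule, the resampling harness — is what this
package actually contributes, and is what the tests pin down.
Consensus over nine independent per-spectrum decisions with accuracy
$p$ yields patient accuracy $\sum_{k\ge5}\binom{9}{k}p^k(1-p)^{9-k}$
(0.901 at $p = 0.7$); the harness reproduces this closed form with a
stub classifier, which is the strongest available end-to-end check of
the voting machinery.

# Metrics

Cancer is always the positive class. Sensitivity and specificity are
exact ratios; an undefined member (empty class) is reported as `NA`,
never imputed. Percentages print half-up to one decimal (92.25 →
"92.3%"), matching the convention of the published tables, and
`counts_matching_percent()` inverts that rounding to recover integer
counts — with 12 cancers and 92 controls the printed 83.3%/87.0% pin
the interim confusion matrix uniquely at TP = 10, TN = 80. AUC is the
Mann–Whitney concordance probability computed from midranks (ties
count 1/2), which equals the trapezoidal area under the empirical ROC
curve; the rank form is primary because it is tie-robust.

# Study design

Sizing a prospective validation study to estimate a proportion $m$
within $\pm d$: the Wald bound
$n_\text{eff} = \lceil z_{1-\alpha/2}^2\, m(1-m)/d^2 \rceil$, inflated
to total recruits by the fraction of the relevant class —
prevalence for sensitivity, $1-$prevalence for specificity. At 2%
prevalence, specificity accrues evidence ~50× faster than
sensitivity, which is why an interim analysis of ~100 recruits already
recalibrates the specificity arm (`interim_update()` re-solves the
bound at the observed metric and subtracts recruits already enrolled).
The published design quotes sample sizes (188–622) that no standard
precision formula we evaluated reproduces; the package documents its
own formula and treats those numbers as context rather than targets.
"Power" enters the plain precision bound only as documentation.

# Numerical choices and degenerate inputs

* Rubber-band hull via Andrew's monotone chain on the ascending-sorted
  grid; interpolation dust below zero (|x| ≤ 1e-12) is clipped.
* Kappa at degenerate margins ($p_e = 1$): defined as 1 when observed
  agreement is perfect, else 0.
* All-zero spectra cannot be L2-normalised (error, not NaN).
* Binning with a non-dividing factor truncates the tail; lengths are
  exact and tested.
* JCAMP-DX support is the fixed-form `(X++(Y..Y))` subset with
  FIRSTX/LASTX/DELTAX/NPOINTS/YFACTOR records; ordinates quantise to
  YFACTOR, so round trips are exact to YFACTOR/2. Truncated files and
  contradictory DELTAX signs are format errors.
* Wide-CSV columns are keyed `patientid_well_replicate`; underscores
  are forbidden inside patient ids to keep the grammar unambiguous.
  Missing cells are errors, never interpolated. Ascending grids are
  flipped to the descending convention and the flip recorded.
* All split/fold/stub randomness derives from the plan's base seed;
  a full run is bit-reproducible on one machine.

# Problem sizes used by the packaged checks

The test suite exercises the full pipeline (simulate → preprocess →
tune → resample → consensus) on a 200-patient cohort at 5 resampling
iterations, and the protocol constants (51 iterations, 5 folds, 9
spectra, 507/217 splits) on small cohorts with a stub classifier;
stub-based consensus checks pool 1000–1500 patient predictions. These
sizes were chosen to keep the default suite comfortably interactive
while leaving every statistical check adequately powered; the full
51-iteration SVM protocol on larger cohorts runs with the same code
paths by changing `resampling_plan()`.

# Known limitations

* Synthetic validation only: equivalence with the published diagnostic
  accuracy cannot be claimed, and is not — the published spectra are
  not available, and the published pre-processing is proprietary.
* The published retrospective specificity appears as 92.0% in one
  place and 92.8% in another in the source study; the package computes
  exact values from counts and takes no side.
* Binary cancer/non-cancer only; tumour-type multiclass is out of
  scope.
* No EMSC, derivative spectroscopy or Mie-scatter correction; the
  preprocessing chain is deliberately the minimal standard one.
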