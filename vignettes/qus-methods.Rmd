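---
title: "Quantitative ultrasound methods for chemotherapy response monitoring"
author: "qusrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound methods for chemotherapy response monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(qusrm)
```

# Scope

`qusrm` implements a quantitative ultrasound (QUS) analysis chain for
monitoring tumor response to neoadjuvant chemotherapy from raw
radio-frequency (RF) ultrasound data: spectral backscatter parameters,
attenuation estimation, scatterer-model fits, parametric-map texture
features, a multi-feature SVM response classifier, and gated group
statistics with Kaplan–Meier survival analysis. Because clinical RF data
cannot ship with a package, every stage is exercised against a synthetic
RF-phantom and patient-cohort simulator with known ground truth. This
vignette documents the models, conventions, parameter choices and their
rationale, and the known limitations.

# The RF signal model and simulator

`simulatePhantomRF()` synthesizes one RF frame from a `PhantomSpec` and an
`AcquisitionConfig`. The phantom is a random medium of discrete point
scatterers (Poisson-distributed axial positions per line, independent
amplitudes); each line is the superposition of a Gaussian-enveloped
round-trip pulse echoed from every scatterer, with frequency-dependent
attenuation applied along the propagation path.

**Decibel conventions.** Attenuation slopes are expressed in
dB/(cm·MHz). A one-way path of length $z$ attenuates *amplitude* by
$\alpha f z$ dB (the $20\log_{10}$ convention), so the round-trip echo
amplitude loses $2\alpha f z$ dB and, equivalently, the received *power
spectrum* is depressed by $2\alpha f z$ dB (the $10\log_{10}$
convention). The simulator and all estimators use this single convention
consistently; `powerDb()` on a `PowerSpectrum` is always $10\log_{10}$ of
linear power.

Defaults in `AcquisitionConfig()`: center frequency 7 MHz, sampling
rate 40 MHz, sound speed 1540 m/s, line pitch 0.2 mm, analysis band
4–9 MHz (the −6 dB band of the simulated pulse, centered at 6.5 MHz).
These are user parameters, not constants.

`simulatePeriodicPhantom(spacingMm, jitter, acq)` adds a regular axial
scatterer lattice (spacing in mm, multiplicative position jitter as a
fraction of the spacing) on top of a diffuse background. The lattice
jitter is drawn independently for every RF line, matching the physical
picture of a 3-D quasi-periodic structure viewed through different
scan-line cross-sections; estimators that aggregate across lines (median
of per-line estimates) are then robust to a single bad jitter
realization.

# Spectral QUS parameters

`tileROI()` partitions a rectangular region of interest into square
sliding windows (side `windowSideSamples(acq)`, ten wavelengths by
default) with fractional overlap (default 0.94).
`blockPowerSpectrum()` computes the Hann-windowed, line-averaged
periodogram of one window.

`normalizeSpectrum(sample, reference, refAttenuation)` implements
reference-phantom normalization: the sample spectrum is divided by the
spectrum of a well-characterized reference phantom acquired with the
same system settings, which cancels the system transfer function, and
the known reference attenuation (round-trip, $2\alpha_r f z$ dB) is
added back so the result reflects tissue backscatter alone.

`fitSpectralParameters()` performs a linear regression of the
normalized spectrum (in dB) on frequency (in MHz) over the analysis
band and reports:

* **SS** — spectral slope, dB/MHz;
* **SI** — spectral 0-MHz intercept, dB;
* **MBF** — midband fit, the regression line evaluated at the band
  center $f_c$, so the identity $\mathrm{MBF} = \mathrm{SI} +
  \mathrm{SS}\, f_c$ holds exactly by construction.

A useful self-test follows from the algebra: normalizing a spectrum by
itself gives a flat 0 dB line plus the reference-attenuation term, so
SS, SI and MBF of a self-normalized spectrum are all zero and the
spectral-difference ACE of identical sample/reference spectra equals the
reference slope.

## Attenuation coefficient estimate (ACE)

`estimateACE()` uses the spectral-difference method. For windows at
depths $z_k$, the log spectral ratio sample/reference at frequency $f$
is $\beta(f) z$-linear with slope $-2(\alpha_s - \alpha_r) f$; a
first regression extracts $\beta(f)$ (dB/cm) across depth for every
frequency, a second regresses $\beta$ on $f$, and
$\widehat{\alpha}_s = \alpha_r - \mathrm{slope}/2$. The fit is flagged
when the depth span or band is too small or the $\beta(f)$ regression
explains little variance. The factor 2 is the round-trip power
convention above.

# Scatterer models

## Spherical Gaussian model (SGM)

`modelBSC()` and `fitSGM()` implement the Gaussian form-factor
backscatter model $\mathrm{BSC}(f) \propto f^4 \exp(-0.827 k^2 a_{\rm
eff}^2)$. Taking $10\log_{10}$ of $\mathrm{BSC}/f^4$ linearizes the
model in $f^2$; a linear fit returns the **average scatterer diameter
(ASD, µm)** from the slope and the **average acoustic concentration
(AAC, dB)** from the intercept. A non-negative slope means the measured
form factor grows with frequency, which the Gaussian model cannot
represent; `fitSGM()` then flags the estimate (Rayleigh-like scattering,
diameter not identifiable). The growth test uses a relative threshold
(`1e-9` of the dynamic range) so float-level noise on an exactly flat
spectrum is not misread as growth.

## Spacing among scatterers (SAS)

`estimateSAS()` detects quasi-periodic scatterer structure from the
spectral redundancy it creates. Per RF line it fits an autoregressive
(Burg) model, locates spectral peaks, and converts the mean peak
spacing $\Delta f$ to a spacing $\mathrm{SAS} = c / (2\Delta f)$
(`sasFromPeakSpacing()`); the frame estimate is the median across
lines.

Defaults and their rationale:

* `arOrder = 40`. The AR spectrum can resolve at most roughly
  `order/2` peaks across the Nyquist span; at 40 MHz sampling an
  order-12 model places poles ~2 MHz apart and cannot resolve the
  ~0.77 MHz comb of a 1 mm lattice. Order 40 resolves 1 mm spacing to
  within a few percent. The cost is a slower fit and the risk of
  spurious poles, which the gating below absorbs.
* `minProminenceDb = 3`, `minPeaks = 3`, `maxSpacingCv = 0.25`. A real
  lattice produces a *comb*: at least three prominent peaks at nearly
  equal spacing (coefficient of variation of successive spacings
  ≤ 0.25). Diffuse speckle occasionally shows a prominent peak *pair*
  but not a regular comb, so requiring three regularly spaced peaks is
  the periodic-vs-diffuse discriminator. Lines with no admissible comb
  contribute no estimate; when no line qualifies the result is returned
  with `defined = FALSE` rather than a number.

Spacings whose comb is finer than the AR resolution (e.g. well above
~1.5 mm at these settings, where $\Delta f$ falls under the pole
spacing) are reported as undefined rather than silently wrong.

# Texture of parametric maps

`computeQusMaps()` turns the per-window spectral/scatterer estimates of
a frame into `ParametricMap` objects (MBF, SS, SI, ASD, AAC, SAS; ACE
is a single per-ROI number and has no map). `quantizeMap()` rescales a
map to `nLevels` (default 16) integer gray levels; `computeGLCM()`
builds one symmetric, normalized gray-level co-occurrence matrix for a
pixel `distance` (1–4) and `angle` (0°, 45°, 90°, 135°; rows are axial,
columns lateral). `glcmConfigurations()` enumerates the full 4 × 4 = 16
grid. `haralickFeatures()` reports contrast (CON), correlation (COR),
energy (ENE) and homogeneity (HOM); `textureFeatures()` averages each
over the non-empty configurations, so each textured parameter
contributes 4 texture features and the 6 mapped parameters contribute
24.

Degenerate inputs have defined conventions rather than errors: a GLCM
with no valid pixel pairs is marked `empty` and skipped in the average;
a constant map yields CON = 0, ENE = 1, HOM = 1 and COR = 1 (with a
warning), COR = 1 being the zero-variance-marginal convention. Masked
(`NA`) pixels simply contribute no pairs.

```{r texture-demo}
q <- quantizeMap(matrix(rnorm(48), 8, 6), nLevels = 8)
g <- computeGLCM(q, distance = 1, angle = 0)
haralickFeatures(g)
```

# Per-patient features and response labels

A scan contributes 31 features (`scanFeatureNames()`): 7 QUS parameter
means (MBF, SS, SI, ACE, ASD, AAC, SAS) and 24 texture features.
`assembleFeatureVector(baseline, week, molecular, scanTime)` builds the
65-entry vector in a fixed, documented order
(`featureVectorNames()`): 31 baseline values (suffix `0`), 31 changes
from baseline (prefix `d`, via `deltaFeatures()`), and the molecular
markers ER/PR/HER2 coded +1/0. Missing components are rejected by name.

`classifyResponse()` encodes the clinical/pathological ground-truth
rules: complete response (CR) when there is neither clinical evidence
of tumor nor invasive residual; partial response (PR) when tumor size
decreased by at least 50% *and* cellularity significantly decreased
(a pathology-supplied input, not computed); non-response (NR)
otherwise. A size decrease of exactly 50% satisfies the PR threshold.

`simulateCohort()` draws a cohort directly at the feature level:
per-patient baselines plus a per-group trajectory effect
(`CohortSpec@trajectoryEffects`, a features × weeks matrix per group)
plus noise, together with recurrence times for survival analysis.
Simulating features directly (rather than through RF synthesis) keeps
cohort-level experiments fast and gives exact control over which
features carry signal; the RF simulator backs the estimator-level tests
instead.

# Response classification

`runResponseClassification()` implements the full protocol on a feature
table (`cohortFeatureTable()`), in one of three feature modes
(`featureModeColumns()`): `combined` (all 65), `qus` (62, no molecular),
`molecular` (3).

1. **Balanced subsampling** (`balancedSubsets()`): to protect the
   three-class SVM from class imbalance, each of `nSubsets` subsets
   draws `min(table(labels))` patients per class without replacement.
   The subsets only vary when group sizes are unequal; with exactly
   equal groups every "balanced subset" is the whole cohort.
2. **Grid search** (`gridSearchSVM()`): RBF-SVM cost/γ selected by
   leave-one-out (LOO) accuracy; ties broken toward the smallest cost,
   then the smallest γ, preferring the least complex model.
3. **Sequential forward selection** (`sfsSelect()`): greedily adds the
   feature that most improves LOO accuracy until `nSelected` features
   are chosen.
4. **Consensus** (`consensusFeatures()`): features ranked by how often
   the per-subset SFS runs selected them.
5. **Evaluation** (`looEvaluate()`): LOO accuracy, per-class
   sensitivity/specificity and the confusion matrix for the consensus
   features.

**LOO class weighting.** Leaving one sample out always
under-represents that sample's class in the training fold; at the small
$n$ typical of response-monitoring cohorts this biases LOO accuracy
measurably below chance on permuted labels. All LOO fits therefore use
inverse-class-frequency weights (`class.weights` in `e1071::svm`),
which restores the permutation null to the nominal $1/k$ level. This is
a statistical-correctness choice in the estimator, not a tuning knob.

# Group statistics and survival

`twoGroupTest()` is gated: Shapiro–Wilk normality on both groups, then
an unpaired $t$ test if both pass (α = 0.05 on the gate) or a
Mann–Whitney $U$ test otherwise. `multiGroupTest()` analogously gates
one-way ANOVA vs Kruskal–Wallis and reports Bonferroni-corrected
pairwise comparisons. The gate is part of the procedure under test, so
its type-I error is verified empirically (it holds the nominal 5% level
within Monte-Carlo error).

`kmEstimate()` / `survivalAt()` wrap `survival::survfit`
(Kaplan–Meier product-limit estimate); `logrankCompare()` wraps
`survival::survdiff`. Hand-computable fixtures (e.g. one event among
four subjects at month 12 gives $S(12) = 3/4$) pin the conventions.

# The pipeline and on-disk formats

`runPipeline(pipelineConfig(...))` chains all stages on simulated data:
phantom RF synthesis, spectral and scatterer estimation, parametric
maps and textures, cohort simulation, classification in all feature
modes, group statistics, and survival summaries, writing CSV/JSON
artifacts and a manifest with MD5 checksums.

RF frames are stored as a plain-text pair: a CSV sample matrix plus a
JSON metadata sidecar carrying the acquisition attributes
(`writeRFContainer()` / `readRFContainer()`). Reading validates the
schema — a missing required attribute or a truncated matrix is an
error, and a round trip is lossless at full double precision.

# Key parameters at a glance

| Parameter | Where | Default | Units | Rationale |
|---|---|---|---|---|
| `centerFrequency` | `AcquisitionConfig` | 7e6 | Hz | breast imaging band |
| `band` | `AcquisitionConfig` | 4–9e6 | Hz | −6 dB pulse band |
| `overlap` | `tileROI` | 0.94 | fraction | dense maps, standard QUS practice |
| window side | `windowSideSamples` | 10 λ | samples | bias/variance trade-off of the periodogram |
| `refAttenuation` | normalization/ACE | 0.576 | dB/(cm·MHz) | typical calibrated reference phantom |
| `arOrder` | `estimateSAS` | 40 | — | resolves ~0.77 MHz combs at 40 MHz sampling |
| `minProminenceDb` | `estimateSAS` | 3 | dB | rejects speckle ripple |
| `minPeaks` | `estimateSAS` | 3 | — | a comb, not a peak pair, indicates periodicity |
| `maxSpacingCv` | `estimateSAS` | 0.25 | — | regular spacing requirement |
| `nLevels` | `quantizeMap` | 16 | — | standard GLCM quantization |
| `nSubsets` | `classifierConfig` | 10 | — | consensus stability vs cost |
| `nSelected` | `classifierConfig` | 3 | — | small-$n$ overfitting guard |

# Problem sizes and runtime

Desk-scale defaults keep every stage interactive: a default phantom
frame is a few hundred lines of a few thousand samples and simulates in
seconds; `runPipeline()` with defaults (10 + 10 + 7-ish patients per
group, 3 × 3 SVM grid) completes in roughly a minute; the full test
suite, which includes 20-replicate recovery studies and 500-replicate
calibration runs, takes several minutes. All stochastic stages accept a
seed, and `deriveSeed(seed, offset)` derives independent per-stage
sub-seeds from one run seed.

# Limitations

* The simulator is 1-D per line (no diffraction, beamforming or
  elevation effects) and uses a Gaussian pulse; it is a test harness
  for the estimators, not a wave solver.
* SAS is undefined, by design, when the spacing's spectral comb falls
  below the AR resolution or no line shows an admissible comb; the
  estimate carries a `defined` flag that callers must honor.
* The SGM cannot represent form factors that grow with frequency;
  such fits are flagged rather than extrapolated.
* ACE needs windows spanning a sufficient depth range; a single depth
  is rejected.
* Classification results at small $n$ have wide confidence intervals;
  the balanced-subset consensus mitigates, but does not remove,
  selection instability.
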