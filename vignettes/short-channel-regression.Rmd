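---
title: "Short-channel regression strategies for fNIRS GLM analysis: models, simulator, and validation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-channel regression strategies for fNIRS GLM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scregress)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical changes in
oxygenated (HbO) and deoxygenated (HbR) hemoglobin through scalp optodes.
Long source--detector channels (25--40 mm) see both cerebral and superficial
extracerebral hemodynamics; short-separation channels (SCs, ~8 mm) see
almost exclusively the superficial compartment. Superficial systemic
physiology — Mayer waves near 0.1 Hz, slower blood-pressure/vasomotion
oscillations, drift — overlaps spectrally with block-design hemodynamic
responses and cannot be removed by temporal filtering alone, so SC signals
are included as nuisance regressors in the general linear model (GLM). The
field disagrees on *how*: toolboxes variously regress the nearest SC, the
most correlated SC, the mean SC signal, or all SC signals (raw or after a
principal component analysis, PCA).

This package implements a complete, simulation-based comparison of ten such
strategies and the two Bayesian validation metrics used to score them:

| id | scope          | method              |
|----|----------------|---------------------|
| 1  | none           | no SC regression    |
| 2  | limited (3 SC) | nearest             |
| 3  | limited (3 SC) | most correlated     |
| 4  | limited (3 SC) | mean                |
| 5  | limited (3 SC) | pooled + PCA        |
| 6  | full (8 SC)    | nearest             |
| 7  | full (8 SC)    | most correlated     |
| 8  | full (8 SC)    | mean                |
| 9  | full (8 SC)    | pooled raw          |
| 10 | full (8 SC)    | pooled + PCA        |

The montage is fixed: 16 long channels (4 left temporal, 7 occipital, 4
right temporal, one right-temporal channel excluded for lacking a
left-hemisphere counterpart) and 8 SCs, one per source. Under the limited
scope only the SCs at sources C5 (left temporal), POz (occipital) and CP6
(right temporal) are available. The exact 10--20 source/detector label
pairs in `build_standard_montage()` are a nominal reconstruction; only ROI
membership, the source attached to each channel, and those three SC sources
enter any computation.

## The forward model (synthetic sessions)

`simulate_session()` composes, per channel and chromophore,

    hemoglobin = neural + share x systemic + sensor noise + motion

and maps the HbO/HbR pair to optical density at 760/850 nm through the same
Beer--Lambert constants the inverse chain uses, then to intensity as
`I = exp(-dOD)`.

**Design.** 45 trials (15 per condition A/V/AV), 10 s stimuli, 8--12 s
uniformly jittered inter-stimulus intervals, 60 s initial baseline, and the
triplet constraint (each consecutive group of three trials contains all
three conditions; order within a triplet is a uniform permutation — the
maximum-entropy reading of "pseudorandomized"). Sampling rate 7.81 Hz,
16 subjects.

**Neural truth.** Occipital channels respond to V and AV, temporal channels
to A and AV. Task regressors are canonical double-gamma HRFs (peak delay
6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6, 32 s
support) convolved with the stimulus boxcars and scaled so that a single
10 s trial peaks at 1; the true HbO amplitude is therefore a peak response
amplitude, default 0.5 uM in model units, with a truncated-normal
between-subject SD of 0.1. HbR amplitudes are `-1/3` of HbO.

**Systemic physiology.** Global components shared by all channels: a
dominant Mayer wave (0.1 Hz), five independent low-frequency
blood-pressure/vasomotion oscillators (0.015--0.08 Hz), cardiac (1.2 Hz),
respiratory (0.25 Hz), and a 1/f-like drift. Oscillators are narrow-band
stochastic processes (slowly drifting phase and amplitude) rather than pure
tones, which would be trivially removable. Every channel loads positively
on every component with log-normal loadings; long channels get a reduced
loading spread (fraction 0.25) because a 25--40 mm photon path averages
superficial physiology over a much larger scalp patch than an 8-mm SC.
Each channel also carries local slow physiological noise that no other
channel shares; on SCs this local noise is larger on average (x3) and
heterogeneous across SCs (log-normal spread 0.8), reflecting variable
scalp coupling. `superficial_share` (default 0.7) scales how much of the
superficial signal reaches a long channel; SCs carry it in full.

**Why these defaults.** The defaults are free parameters chosen once to
place the simulator in the regime the method comparison is about, and each
mechanism is physiologically motivated:

* Systemic amplitudes roughly an order of magnitude above the neural
  amplitude make the uncorrected HbO pipeline fail — with purely
  task-unlocked noise (the simulator deliberately contains no task-locked
  systemic component), confounding arises only from random spectral
  overlap, which is weak per micromolar of noise, and superficial dominance
  of this magnitude is the well-documented situation in adult fNIRS.
* The multi-dimensional in-band oscillator bank is what defeats
  single-regressor strategies: a single SC can always cancel *one*
  dominant component (its regression coefficient adapts), but not a
  subspace.
* Heterogeneous SC quality is what penalizes trusting one SC (nearest or
  most correlated) and rewards pooling, which averages local SC noise away
  and, with PCA, separates it from the shared components.
* The small HbR systemic fraction (1/20) reproduces the robust empirical
  finding that HbR is far less contaminated by systemic physiology than
  HbO, so HbR results change much less across pipelines.

What the simulator does **not** emulate: photon transport and partial
volume effects (amplitudes are model units, labeled uM only through the
fixed-pathlength Beer--Lambert convention), task-locked systemic responses
(stimulus-evoked arousal), spatially structured noise beyond the
global/local dichotomy (e.g. the midline sagittal-sinus effect), and any
eye-movement or stimulus-content structure. Passing the package's tests
therefore shows that the pipeline ranking follows from the stated noise
structure — not that it holds for every real dataset.

**Motion.** Sparse exponential-decay spikes (0.5/min, ~30 uM) and rare
baseline steps (0.1/min, 5 uM), random sign, shared across chromophores at
a 1/3 ratio.

## Preprocessing

`preprocess_session()` applies, in a fixed order enforced by contract:

1. **Optical density**: `dOD = -ln(I / mean(I))` per channel and
   wavelength.
2. **TDDR** (temporal derivative distribution repair): the signal is split
   at 0.5 Hz; on the low-frequency part the derivative's location and
   scale are estimated by iteratively reweighted robust estimation (Tukey
   biweight, tuning constant 4.685, scale 1.4826 x median absolute
   deviation, at most 50 iterations). Derivative samples rejected by the
   biweight — deviations beyond the tuning constant times the robust
   scale — are replaced by the robust mean; all others pass unchanged.
   This realizes the method's defining property that only statistically
   improbable rates of change are corrected: a variant that multiplies
   *every* derivative sample by its weight attenuates clean band-limited
   signals by several percent (the biweight is below one everywhere) and
   badly distorts noise-free block designs, which would make unbiased
   parameter recovery impossible. Sharp spikes
   faster than the split survive partially in the high-frequency remainder
   and are eliminated by the subsequent band-pass.
3. **Band-pass 0.01--0.12 Hz**: fourth-order Butterworth low-pass and
   high-pass in cascade, each applied forward-backward (zero phase,
   effective eighth order) with reflective edge padding and mean removal
   before the high-pass. A directly designed band-pass of this relative
   bandwidth at 7.81 Hz is numerically unstable (pole radius > 1), which
   is why the cascade realization is used. The test suite verifies at
   least 40 dB attenuation at the cardiac frequency, DC rejection, a
   passband deviation under 5%, and the zero-phase property.
4. **Beer--Lambert inversion**: per time point the 2x2 system
   `dOD_lambda = sum_c eps(lambda, c) dC_c d ppf` is solved with
   Gratzer-compiled extinction coefficients at 760/850 nm, the
   source--detector distance `d` in cm and the fixed pathlength factor
   `ppf = 0.1` applied identically at both wavelengths. Whether `ppf`
   represents a differential pathlength factor or a combined
   partial-volume term only rescales the recovered concentrations; the
   forward and inverse models share the convention, so recovery tests are
   unit-consistent by construction.

The first and last stretches of the filtered series retain mild edge
effects from the padded zero-phase filtering; nothing is trimmed, matching
the use of the full series in the GLM.

## GLM and the ten strategies

Per subject, channel and chromophore, `fit_ols()` solves the OLS problem
with a rank-revealing QR decomposition (minimum-norm fallback with a
warning on rank deficiency). The design always contains the three
HRF-convolved condition regressors plus an intercept — without an
intercept, PCA column-centering would change the nuisance span and break
the raw-vs-PCA pooling equivalence. The condition regressors are passed
through the same band-pass as the data (matched linear filtering): the
data's slow components are attenuated by preprocessing, and the estimator
is unbiased only if the design lives in the same filtered space. No
prewhitening or autocorrelation correction is applied (plain OLS is the
analysis under study).

Nuisance sets per strategy: nearest and most-correlated contribute one
same-chromophore SC trace (correlation computed over the whole recording
on preprocessed traces, ties broken by lowest SC id); mean contributes the
SC average separately for HbO and HbR (2 regressors); pooled raw
contributes every SC trace of both chromophores (16 under the full scope);
pooled PCA contributes all principal components of the column-centered
concatenated SC matrix (6 limited / 16 full), computed once per subject by
SVD without variance scaling and reused across channels and chromophores.
Components with singular values below 1e-10 of the largest are dropped
with a warning. Because the PCA span equals the raw span, pipelines 9 and
10 yield identical condition betas up to numerical precision whenever the
SC matrix is full rank — any difference between them in real toolboxes
must come from implementation details, not from the model.

## Validation metrics

Betas are compared across subjects with directional
Jeffreys--Zellner--Siow Bayes-factor t-tests: a Cauchy prior of scale
sqrt(2)/2 on the standardized effect, truncated to the expected direction,
integrated against the noncentral-t likelihood by adaptive quadrature
(relative tolerance 1e-8; the test suite checks agreement with an
independent fine-grid integration of the equivalent g-mixture form to
1e-4). The prior family and scale are the de-facto defaults of standard
Bayesian t-test software; any published Bayes-factor values computed with
a different prior will differ, which is a known divergence risk when
comparing numerical BF values across reports. No multiplicity correction
is applied, consistent with the Bayesian framing. Evidence categories:
BF10 in (1, 3] weak, (3, 10] positive, (10, 100] strong, > 100 decisive.

* **Metric 1 (emergence)**: one-tailed one-sample tests against zero —
  conditions A and AV in temporal channels, V and AV in occipital
  channels; positive direction for HbO, negative for HbR. A channel is
  emergent if any tested condition exceeds BF10 = 3.
* **Metric 2 (contrasts)**: within emergent channels only, one-tailed
  two-sample tests between conditions (A vs V and AV vs V temporally;
  V vs A and AV vs A occipitally), in the expected direction per
  chromophore. Two-sample (not paired) tests are used deliberately,
  following the wording of the analysis being replicated, although the
  within-subject design would naturally admit a paired test; non-emergent
  channels carry `NA` contrasts (not evaluated, as opposed to
  evaluated-and-negative), so metric-2 counts can never exceed metric-1
  counts.

The one-sided BF10 > 3 rule is calibrated: under null betas its
per-condition-test false-positive rate stays below 5% (checked with 200
replicates at 16 subjects by the test suite and recomputed by the
acceptance script).

## Block averages

`epoch_and_average()` provides the descriptive counterpart to the GLM:
epochs from -5 to 25 s around onsets, baseline-centered on [-5, 0],
averaged over epochs within condition, then channels within ROI, then
subjects (with equal epoch counts these orders commute), standard errors
across subjects. `corrected_block_average()` residualizes each long
channel on the pipeline's nuisance set (plus intercept) before epoching,
so the curves reflect the corrected signals; the projection is idempotent
and the no-SC configuration reduces to the plain average. On simulated
data the sign of the mean HbO curve area over [0, 15] s concords with the
sign of the mean HbO beta.

## Numerical choices and degenerate inputs

* Baseline intensity is 1 per channel and wavelength; only ratios matter
  after the optical-density conversion, and the forward model errors out
  if the optical density would overflow (non-positive intensity).
* `tddr` requires at least 10 samples and finite input; with a zero robust
  scale (constant derivative) it returns the input unchanged.
* With only a handful of trials and *literally* zero noise the robust
  scale inside TDDR degenerates (the derivative is mostly exactly zero)
  and genuine response transitions can be rejected; parameter-recovery
  guarantees therefore refer to the study-sized 45-trial design, and any
  realistic sensor noise removes the degeneracy.
* `fit_ols` refuses an all-constant response with an all-constant design;
  group-level metrics require at least 3 subjects (a single-subject
  comparison runs with group statistics disabled and a warning).
* Cohort determinism: every subject draws an independent child seed from
  the master seed; two runs with the same master seed are identical.

## Problem sizes used by the test suite

Unit tests run on 3-trial, 2--4-subject sessions, which exercise every
code path in seconds; the end-to-end ranking checks run the full
16-subject, 45-trial, ten-pipeline comparison over five seeded replicates,
and the calibration check uses 200 null replicates. These sizes are the
package's own validation design; `run_comparison()` itself has no size
restrictions.
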