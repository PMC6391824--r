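---
title: "Methods: quantifying cerebellar ataxia from wearable IMU recordings"
author: "ataximu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cerebellar ataxia from wearable IMU recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataximu)
```

## The problem

Cerebellar ataxia impairs the coordination of voluntary movement. At the
bedside it is assessed with three standard tests — repetitive finger-to-nose
reaching (FNT), rapid alternating pronation–supination of the hand (DDK),
and sliding the heel along the opposite shin (HST) — and the severity of
what the clinician sees is scored subjectively (here on a three-class
scale: 0 = control, 1 = mild, 2 = significant ataxia). `ataximu`
implements an objective counterpart: a wearable inertial measurement unit
(tri-axial accelerometer + gyroscope, 50 Hz) records the limb during each
test, and a fixed signal-processing and statistical pipeline turns the
recording into frequency-domain features, a severity score, and
cross-validated classification metrics.

The clinical signature the pipeline targets is that ataxic subjects repeat
these alternating movements *more slowly* and *more variably* than
controls, with tremor superimposed. In the frequency domain this appears
as a lower, broader dominant peak of the movement rhythm.

## Pipeline overview

Per subject, test and limb:

1. **Preprocessing** — per channel: sensor-bias removal (mean
   subtraction, which also removes gravity from the accelerometer Z
   channel and the gyroscope zero-rate offset), a 10 Hz low-pass, then a
   6th-order Butterworth band-pass. Both filters are applied
   forward–backward (zero phase).
2. **Kinematics** — five measures per axis: linear acceleration `A`
   (accelerometer), linear velocity `V` (trapezoidal integral of `A`,
   linearly detrended), angular velocity `Av` (gyroscope), angular
   acceleration `Aa` (five-point central difference of `Av`) and angle
   `An` (trapezoidal integral of `Av`, linearly detrended).
3. **Spectral features** — for each limb × measure × axis, the FFT
   magnitude spectrum yields the resonant frequency `RF` (location of the
   largest in-band peak) and its magnitude `MR`:
   2 kinds × 5 measures × 3 axes × 2 limbs = **60 features** per subject
   and test, named e.g. `RF_DDK(L)^{Y,Av}`.
4. **Feature selection** — per feature, a two-sided Welch t-test of
   patients (classes 1, 2) against controls; features with raw p < 0.05
   are kept. Pearson correlations against the clinical score are reported
   for every feature, and |r| ≥ 0.5 is flagged as a strong association.
5. **Separation and severity scoring** — features are z-scored and
   projected by PCA; the mean silhouette coefficient over severity
   classes quantifies separation; a Fisher linear discriminant on the
   leading components produces the severity score, whose Pearson
   correlation with the clinical score is the headline agreement measure.
6. **Validation** — stratified 10-fold cross-validation (3-class
   accuracy; sensitivity/specificity at the patient-vs-control
   binarisation) and a ROC/AUC on the out-of-fold discriminant score.

## Numerical and design choices

**Filter order and application.** A "6th-order band-pass" is the overall
order (a 3rd-order low-pass prototype transformed to a band-pass). Filters
are applied forward and backward so the magnitude response is squared and
the phase cancels; peak *timing* in the kinematic traces is therefore
preserved, at the cost of a non-causal (offline) operation — appropriate
for recorded test bouts. Edges are handled by odd-reflection padding of
3 × order samples, and filtering is done around the sequence's initial
level so constants map to constants exactly and start-up transients stay
small. `bandpass_response_squared()` exposes the designed response; it
matches the analytic Butterworth curve (with bilinear prewarping) to well
within 2 %.

**Band assignment.** The 2–5 Hz band suits the alternating-movement test
(DDK), whose rhythm sits near 2.3–3.6 Hz. The finger-to-nose and
heel-to-shin rhythms are slower (roughly 0.5–1.2 Hz and 0.5–0.8 Hz), so a
2–5 Hz band would remove the movement itself; the per-test defaults in
`default_band()` are therefore 0.5–5 Hz (FNT) and 0.3–5 Hz (HST). A
5–25 Hz drift-reduction variant is expressible through the same
configuration (the upper edge is clamped to 0.99 × Nyquist at 50 Hz).
Both the band and the resonant-peak search band (default 0.25 Hz up to
the band's upper edge, excluding residual DC) are configuration, not
claims about the only valid choice.

**Differentiation and integration.** Angular acceleration uses a
five-point (fourth-order) central difference: at 3 Hz / 50 Hz a
three-point difference already attenuates amplitudes by 2.3 %, while the
five-point stencil is accurate to < 0.1 %, keeping the closed-form
`2*pi*f` amplitude relation within 2 % end to end. Integrals use the
cumulative trapezoid with zero initial condition followed by linear
detrending, which suppresses the drift that integration of biased or
noisy signals accumulates without modelling sensor drift explicitly.

**Spectrum.** Spectra are computed on mean-removed signals, zero-padded
to the next power of two at least 4 × the signal length (RF granularity
≤ fs/(4n) ≈ 0.012 Hz for a 15 s bout), rectangular window (the signal is
already band-passed), one-sided raw magnitudes. Peak ties break toward
the lower frequency, the direction of clinical interest. `MR` carries no
2/N normalisation; any constant factor cancels in cohort comparisons.

**Statistics.** Welch's unequal-variance t-test is the default test
family (a Mann–Whitney option exists behind `family = "wilcoxon"`); raw
p < 0.05 without multiple-testing correction mirrors the selection rule
the pipeline models, with a Benjamini–Hochberg switch available but off
by default. The silhouette uses Euclidean distances with the convention
that singleton-class points contribute 0. The Fisher discriminant
regularises the within-class scatter with a trace-scaled ridge
(default 1e-4) because with ~70 subjects and 60–120 features the scatter
is singular; the first discriminant is oriented so controls score
highest, giving the (negated) severity score a stable positive
association with the clinical scale. The number of components passed to
the LDA is the smallest count reaching 95 % cumulative explained
variance, capped at 3. The ROC is computed on the patient-vs-control
binarisation of the out-of-fold discriminant score (a 3-class ROC is not
defined); AUC equals the Mann–Whitney U statistic divided by the product
of group sizes, ties stepping the curve diagonally.

## The synthetic-motion generator

No patient recordings are distributable, so `simulate_session()` and
`simulate_cohort()` generate the study conditions. The movement model is
an oscillation whose frequency and amplitude are redrawn every cycle
(phase kept continuous), plus an optional tremor harmonic at twice the
movement frequency, white sensor noise on every channel, a constant
gyroscope bias, and gravity on accelerometer Z. The primary channel is
gyroscope Y for the upper-limb tests (pronation–supination axis) and
accelerometer Z for heel-to-shin; all other channels receive a 0.2
cross-talk copy so every axis carries signal, as real sensors do.

Class presets encode the qualitative clinical picture only: base
frequency strictly decreasing with severity (DDK 3.6/2.9/2.3 Hz,
FNT 1.2/0.9/0.7 Hz, HST 0.8/0.6/0.5 Hz), cycle-to-cycle jitter 2/6/12 %
of base, tremor amplitude ratio 0/0.1/0.25. Amplitudes are constant
across classes: the class signal is tempo and variability, not vigour.
On top of the presets, each simulated subject draws an individual tempo
and vigour factor (6 % relative s.d.) — without this, classes would be
trivially separable point masses; with it, class overlap is realistic
while classification remains strong. These numbers are configuration
surfaced in `motion_params()`/`default_params()`, chosen once as
plausible magnitudes; the published study reports no quantitative
patient-vs-control frequency gap to calibrate against.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: goal-directed endpoint geometry (dysmetria),
biomechanically coupled multi-axis trajectories, orientation dynamics
(quaternions), non-stationary fatigue or pauses, and sensor dropout. The
simulator validates the *pipeline*; clinical validity claims require
clinical data.

A structural consequence worth understanding: all 60 features of a
simulated subject derive from a handful of latent quantities (the
subject's tempo and vigour, and one realised signal per limb). Feature
columns are therefore strongly dependent, and in null experiments
(identical presets across classes) significant-feature counts arrive in
whole-cohort bursts rather than as independent coin flips: the
*marginal* keep-rate of any single feature is calibrated at the nominal
α, while the *count* of kept features per cohort is heavily
over-dispersed relative to a binomial with 60 independent trials. Real
multi-feature movement data behaves the same way, which is one reason raw
per-feature p < 0.05 selection over-selects in practice.

## Degenerate inputs and edge rules

Constant sequences: bias removal maps them to zero; the spectrum of a
mean-removed constant is all-zero and `resonant_peak()` reports a
no-peak error naming the offending feature. Zero-variance features
receive unit scale in z-scoring (they carry no information either way)
and p = 1 in selection when group means agree. Cross-validation reduces
k to the smallest class count with a recorded warning rather than
failing. All simulation, fold assignment and reports are deterministic
under a fixed seed, and report files contain no timestamps, so identical
configuration and seed reproduce byte-identical output.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale, chosen as the smallest
sizes at which each property is meaningful: cohorts of 15/15/15 for
severity recovery (10 seeds), 10/10/10 for the null-calibration and
perfect-separability checks, 6/6/6 for end-to-end determinism, and the
study's 31/20/19 in `scripts/acceptance.R`. Recordings are 15 s at 50 Hz
(750 samples), the duration of a typical test bout.

## Worked example

```{r example, eval = FALSE}
library(ataximu)

cfg <- pipeline_config(
  synthesis = list(n_per_class = c(31, 20, 19), seed = 7),
  tests = c("FNT", "DDK"), combine = c("FNT", "DDK"),
  k = 10, cv_seed = 1, out_dir = "reports"
)
res <- run_pipeline(cfg)
res$DDK$cv          # accuracy, TPR/FPR, confusion matrix
res$DDK$roc$auc     # out-of-fold AUC
readLines(file.path("reports", "run_log.txt"))
```

## Known limitations

* The severity scale is ordinal but the discriminant treats classes as
  nominal; the score–severity correlation is a monotone-association
  summary, not a calibrated measurement of disease progression.
* Silhouette values depend on the number of retained components and on
  z-scoring; they are comparable within a configuration, not across
  configurations.
* Feature selection is univariate; interacting features that separate
  cohorts only jointly are invisible to it (the PCA/LDA stage uses the
  full feature set and partially compensates).
* DTW and spectral entropy are provided as comparison feature families;
  their operands in the published study are not recoverable, so the
  implementations here (left-vs-right magnitude-profile DTW; Hann-window
  normalised spectral entropy) are reasonable stand-ins, clearly not
  reproductions.
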