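---
title: "Whole-trajectory gait deviation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-trajectory gait deviation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitspm)
```

## The problem

Clinical gait analysis compares a patient's joint moment and joint angle
trajectories — smooth curves over the gait cycle — against a normative
reference cohort. Comparing such curves point by point with ordinary tests
inflates the family-wise error rate: at 101 time-normalised nodes and a 5%
pointwise alpha, several "significant" nodes are expected under the null.
One-dimensional Statistical Parametric Mapping (SPM) addresses this by
treating the whole trajectory as a smooth random field: a test statistic is
computed at every node, and a *single* critical threshold is chosen so that
the probability that the field's maximum exceeds it under the null is the
desired alpha. `gaitspm` implements this machinery for the five comparisons
a gait laboratory routinely makes (pre/post intervention against a
reference, and pre against post, paired or not), for both individual
movement components (t fields) and the joint's full 3-component rotation
vector (Hotelling's T² fields), and condenses the outcome into a
fold-of-threshold severity map intended for clinicians rather than
statisticians.

## Data model

One CSV file holds one scalar component: one measure (moments or
kinematics) × limb × joint × dimension × condition. The file has a single
header line (its content carries no semantics and is ignored) followed by
one row per trial; reference files carry one row per reference subject
(that subject's trial average). Rows are time-normalised to 101 nodes so
node *i* sits at exactly *i*% of the gait cycle. Non-numeric or empty cells
become `NaN` and are tracked in a per-node missing mask; a dataset with
arbitrarily many absent files, or recordings that stop partway through the
cycle, loads and analyses without error — what cannot be computed is
skipped with a structured note.

Internally matrices are indexed 1..101 as is natural in R; every reported
quantity (cluster intervals, severity maps, plots) uses the 0–100
percent-of-cycle scale.

## Preprocessing

* **Time normalisation** — piecewise-linear interpolation onto 101 equally
  spaced points over the row's finite support. Linear interpolation is the
  default because it cannot overshoot (no ringing on sharp moment peaks)
  and is exactly testable: it reproduces affine rows to machine precision
  and never leaves the observed range. A natural-spline option exists for
  users who prefer smoother resampling. A trailing missing run maps to a
  proportional trailing run of missing nodes — a recording covering 60% of
  the cycle stays a 60% recording.
* **Amplitude scaling** — division by a positive factor, typically body
  mass in kg, turning joint moments in Nm into the conventional Nm/kg.
  The factor may be per-trial for pooled data.
* **Sign flipping** — negation of components recorded under a laboratory
  convention that disagrees with the ISB positive directions, declared as
  a set of component patterns in the preprocessing spec.

## Statistic fields

At every node *q* with complete, non-degenerate data:

* two-sample t: pooled-variance statistic with ν = n₁ + n₂ − 2;
* paired t: on row-wise differences, ν = n − 1;
* two-sample Hotelling's T²:
  (n₁n₂/(n₁+n₂)) · d̄ᵀW⁻¹d̄ with pooled covariance W, ν = n₁ + n₂ − 2;
* paired Hotelling's T²: n · d̄ᵀS⁻¹d̄ on paired differences, ν = n − 1.

The number of components p is whatever the dataset provides for that joint
(1–3); with p = 1 the T² field is exactly the squared t field, which is
both a tested invariant and the path taken when, say, a simple ankle model
provides only the sagittal dimension. Nodes with zero variance (or a
singular covariance) are masked with a warning, never an error; the
reference rows being subject averages are treated as ordinary observations,
so the error degrees of freedom refer to subjects on the reference side and
trials on the patient side — a deliberate, documented simplification rather
than a mixed-effects correction.

## Family-wise inference

**Random Field Theory.** The critical threshold z\* solves
E[EC](z\*) = α, where the expected Euler characteristic of the excursion
set of a smooth 1D field is the tail probability plus R·ρ₁(z\*), R the
resel count (valid extent divided by the estimated FWHM) and ρ₁ the 1D EC
density of the field type. The first-order form (rather than
1 − exp(−E[EC])) is used; at conventional alphas the difference is
negligible and the choice is slightly conservative. T² fields are
thresholded through the exact pointwise transform
F = ((ν − p + 1)/(νp))·T² with (p, ν − p + 1) degrees of freedom and the
1D F-field EC density, then mapped back to the T² scale. The F density's
constant is pinned by the requirement that a p = 1 T² field reproduce the
|t| threshold squared — an identity the test suite checks directly, and
that the permutation engine validates independently.

t tests are two-sided by default (threshold on |t|, i.e. α/2 per tail):
clinical deviations can go in either direction. T² is inherently
one-sided.

**Smoothness.** Residuals (per-group mean-removed) are normalised to unit
variance per node; the mean squared gradient v̄ between adjacent valid
nodes gives FWHM = √(4·ln 2 / v̄), clipped to [1, Q − 1]. White noise has
v̄ → 2 and lands at the rough-field floor √(2 ln 2) ≈ 1.18; fields
synthesised at FWHM 20 are recovered within a few percent. Resels are
summed over contiguous valid runs, so a recording missing its last 40%
contributes only its observed extent.

**Permutation alternative.** The (1 − α) empirical quantile of the
permutation distribution of the field maximum (max |t| or max T²),
permuting group labels (two-sample) or difference signs (paired). Designs
with few distinct relabellings are enumerated exhaustively; otherwise a
seeded random subset of `n_perm` relabellings is drawn, making runs exactly
reproducible. If fewer distinct relabellings exist than 1/α the requested
alpha cannot be resolved and the function says so. On the synthetic fields
below, RFT and permutation thresholds agree within a few percent, which is
the package's standing cross-validation of the analytic densities.

## Severity maps

The clinician-facing output is folds of threshold per node:
s(q) = 0 where |z(q)| ≤ z\*, otherwise min(|z(q)|/z\*, clip), with clip 4
for individual components and 8 for the combined 3D bar under the default
legend. One fold anchors "just significant"; the ratio grows with the
strength of evidence against the reference at that phase of the cycle.
This threshold-relative reading is the package's central display decision:
the legend could in principle be anchored to a normative band instead, but
a threshold ratio needs no extra calibration data, is invariant to joint
rescaling of the statistic and its threshold (a tested property), and
collapses to the familiar "significant vs not" at 1 fold. Strict exceedance
defines significance, so severity is positive exactly on the
supra-threshold cluster set. For the legend the interval (1, clip] is
binned uniformly into `n_levels` colour levels (default 8); level 0 is
non-significant, −1 marks masked nodes; three colormaps (cool-to-warm, jet,
viridis) are provided as a thin presentation layer.

## The synthetic generator

`simulate_gait_dataset()` produces datasets in exactly the CSV layout the
loader reads: smooth Gaussian noise (white noise convolved with a Gaussian
kernel, reflecting boundaries, renormalised to exact pointwise SD) around
illustrative low-order sinusoid templates, with optional Gaussian-bump
deviations injected at a chosen phase, width and amplitude. Defaults are
chosen once as a plausible clinical comparison: 20 reference subjects
(matching common normative cohort sizes), 10 trials per patient condition,
101 nodes, residual FWHM 20 nodes (typical for filtered gait waveforms),
noise SD 0.5 on the template scale. Reference rows emulate subject averages
of 5 pseudo-trials whose trial-level SD is inflated by √5, so the
*delivered* rows have the same pointwise SD and smoothness in every
condition — under the null, all conditions are equal in distribution, which
is what makes the generator a valid calibration substrate. The generator
emulates the format, smoothness and group structure of gait data — not its
biomechanics: templates are not physiological, noise is stationary and
Gaussian, and trials are independent. Calibration and power results on it
therefore validate the statistical machinery, not claims about any
particular patient population.

## Numerical choices and degenerate inputs

* Zero variance is detected relative to the data scale (SD ≤ 10⁻¹² of the
  mean absolute level), so constant shifts whose differences carry only
  rounding residue are caught; affected nodes are masked with a warning.
* Cluster membership requires strict exceedance; boundary equality is
  non-significant.
* The RFT root is found by bisection-safe `uniroot` on the decreasing tail
  of E[EC], bracketed from the uncorrected quantile upward, tolerance
  1e-10.
* Severity and cluster output ignore nothing silently: every skipped
  component, degenerate node or absent condition appears in the report's
  notes.
* Statistic fields are serialised to JSON with 17 significant digits so a
  re-read reproduces them bit-exactly.

## Problem sizes used in the shipped checks

The package's own verification uses sizes a laptop handles in seconds:
type-I error calibration with 1000 simulated null datasets (10 + 10 trials,
FWHM 20), threshold concordance over ~10 datasets with 1000–2000
permutations each, smoothness recovery from 50 fields, and 200 end-to-end
seeded runs for power/localisation of a 10σ bump (width 5 nodes) at 50% of
the cycle, which is detected essentially always with median localisation
error well under the bump width.

## Known limitations

* No cluster-level p-values or set-level inference; the threshold is the
  inferential object, matching the severity display.
* No non-sphericity or mixed-model correction for the reference rows being
  subject averages.
* Missing data are tolerated node-wise; no registration or imputation is
  attempted, and inter-node gaps shorter than the kernel can fragment
  clusters.
* The permutation engine permutes whole trials; it assumes exchangeability
  across the compared groups.
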