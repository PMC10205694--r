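---
title: "Methods: quantitative disc relaxometry and cohort models in nprelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative disc relaxometry and cohort models in nprelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nprelax)
```

## The problem

Lumbar intervertebral discs lose proteoglycan and water long before
structural damage becomes visible on conventional T2-weighted MRI. Spin-lock
(T1ρ) relaxation times track that biochemical state: a healthy, hydrated
nucleus pulposus (NP) relaxes slowly (high T1ρ), a degenerated one quickly.
`nprelax` implements the full quantitative pathway from raw multi-spin-lock
image stacks to cohort-level statements about how NP-T1ρ varies with age,
sex, spinal level and clinical group (chronic low back pain vs.
asymptomatic), together with a synthetic phantom and cohort generator that
gives every stage a known ground truth.

## Voxel-wise relaxation mapping

Each voxel's signal across spin-lock times follows the mono-exponential
decay

$$SI(TSL) = S_0 \, e^{-TSL / T_{1\rho}},$$

and analogously for T2 with echo time in place of spin-lock time. The fit in
`fit_monoexponential()` / `fit_map()` exploits the model's structure: for a
fixed relaxation time $T$ the amplitude $S_0$ enters linearly and has a
closed-form least-squares solution, so the residual sum of squares is a
one-dimensional function of $T$ (variable projection). The fitter scans that
profile on a log-spaced grid across the clamp interval and refines the best
bracket with Brent minimisation. Compared with a Levenberg–Marquardt
iteration started from the log-linear regression, this needs no starting
values, cannot diverge, and locates the global minimum within the clamp; a
dedicated test confirms agreement with a dense two-dimensional brute-force
grid search to better than 0.05 ms. Each series is normalised by its mean
signal before fitting, which makes the estimated $T$ exactly invariant to
intensity rescaling.

Numerical safeguards:

* **Clamp** $T \in [1, 500]$ ms. Observed NP means in adult lumbar discs
  span roughly 35–150 ms, so the clamp is generous; a fit landing on a bound
  (e.g. a flat, non-decaying series) is flagged invalid rather than
  truncated silently.
* **Noise threshold.** Voxels whose mean signal falls below
  `3 × noise_sigma` are not fitted (background masking). `noise_sigma = 0`
  disables the mask.
* **Sentinels.** Invalid voxels carry `NA` in every parameter volume.
* Two-point series are solved by the exact log-ratio identity; they exist
  for testing only.

The default spin-lock grid `c(2, 10, 20, 40, 60)` ms is a configuration
default, overridable wherever a series is constructed.

## Geometric NP extraction

Disc segmentations arrive as labelled voxel masks over the mid-sagittal
slices. For each disc, voxel coordinates (converted to mm via the voxel
spacing, pooled across slices) are recentred at their centroid and rotated
into the principal frame of the second-moment — rotational inertia — tensor
(`principal_axes()`, `standardize_disc()`). The major axis is the disc's
anterior–posterior axis; the sign convention points it anterior→posterior.
The NP is then `extract_np()`: voxels whose principal-frame AP coordinate
lies within the central 40% of the disc's AP extent, boundary inclusive.

Design choices made where the procedure was genuinely open:

* **Extent, not quantile.** "Central 40%" is measured along the AP bounding
  interval in the principal frame, not as a 40% voxel-count quantile; the
  two coincide for rectangles but differ for tapered shapes.
* **Pooled slices.** One principal frame per disc across all mid-sagittal
  slices, because one NP biomarker is reported per disc.
* **No resampling.** Voxels are classified by the rotated coordinates of
  their centers; intensities are never interpolated, so biomarkers are
  computed on original voxel values.
* **Ties.** Near-isotropic discs (eigenvalue ratio < 1.05) keep the
  identity rotation and are flagged; collinear or <3-voxel sets are errors.

Rotation invariance is verified end-to-end: rotating a phantom disc by
10–45° moves the NP-T1ρ mean by less than 0.5 ms. One known discretisation
effect: for elliptical masks the NP voxel fraction at the 40% setting sits
at ≈ 0.50–0.52 (continuum value 0.4955), slightly above the 0.50 that holds
for boxier convex shapes; this is a property of voxelised ellipses, not of
the extraction rule.

## Per-disc biomarkers

`disc_biomarkers()` reduces a map and an NP region to the per-disc record:
mean and sample (n−1) SD of valid NP voxels, whole-disc mean, and the valid
voxel count. Records with fewer than 10 valid NP voxels (configurable) are
flagged incomplete and excluded from models, not errored. Validity
filtering itself can be disabled (`filter_valid = FALSE`) since it is an
addition of this implementation.

## Cohort statistics

The primary outcome is the mean NP-T1ρ per disc. Two model families:

* `fit_mixed_model()` — a linear mixed model over all discs with a random
  subject intercept and the full factorial fixed-effects structure
  age × sex × level × group (all two- and three-way interactions plus the
  four-way term). Estimation is REML via `lme4`; inference is Wald with
  two-sided α = 0.05 and no multiplicity correction.
* `fit_levelwise_model()` — per-level OLS of outcome on age, sex, group and
  age × group, motivated by the three-way age × level × group interaction:
  it lets the age slope differ by group within a level.

Coding conventions: age is centred at the sample mean; sex and group are
effect-coded (±0.5); level is treatment-coded with L1–L2 as reference.
Because interactions are present, single coefficients are not the quantities
of interest; `marginal_effects()` derives them by averaging design rows over
the observed covariate distribution:

* the **marginal age slope** is the observation-weighted mean of
  cell-specific slopes (equivalently the average derivative of the fitted
  surface with respect to age);
* the **sex and group contrasts** are mean counterfactual prediction
  differences (each observation switched to male vs. female, control vs.
  cLBP), i.e. age-adjusted marginal contrasts.

`predict()` gives population-level predictions with Wald intervals;
omitting sex returns the sex-averaged prediction. The outcome column is a
parameter, so the entire battery reruns on NP-T2 (`outcome = "np_t2_mean"`)
without code changes.

Supporting tests: Pearson correlations of outcome with age per group×level;
a hand-implemented Cochran–Armitage trend test (standard score statistic,
two-sided normal p, default scores 1..K) verified against a 20,000-draw
permutation oracle; Student's t and a continuity-uncorrected chi-square in
`group_comparison_suite()`; per-grade density histograms of NP voxels; and
the squared voxel-wise Pearson correlation between T1ρ and T2.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code: it defines the study
conditions under which the statistical machinery is verified. Defaults
emulate a 133-subject design (53 control / 80 cLBP; 26 F/27 M and
35 F/45 M within group; truncated-normal ages 43.9 ± 13.4 years on
[19, 75]; L1–L2 out of the field of view for 15 subjects — 6 control,
9 cLBP — leaving 650 discs). The observed disc value is

```
level-group mean + slope · (age − 43.9) + sex term + subject intercept + residual
```

with control level means {81.0, 79.0, 77.0, 75.0, 69.8} ms, cLBP deficits
{4.5, 4.2, 4.0, 3.8, 11.3} ms, slopes −1.0 ms/yr everywhere except
−0.3 ms/yr for cLBP at L5–S1, a male–female gap of 8.1 ms, subject-intercept
SD 12 ms and residual SD 13 ms. The L5–S1 values fix the age-30/age-50
predictions near 84, 64 and 57 ms by construction; the L1–L4 level means are
calibrated (not printed anywhere) so the group marginal means land near
76.4 / 70.8 ms. The variance budget
(13.4² · slope² + 4.05² + level spread + 12² + 13² ≈ 22.5²) is itself a
tested property.

Pfirrmann grades are banded thresholds on the true (noise-free) NP-T1ρ —
≥95 → I, 80–95 → II, 62–80 → III, 48–62 → IV, <48 → V — with a 10%
one-grade misread probability; these bands exist only to exercise the trend
test and histogram analyses and are an invention of the generator. Because
grades derive from subject-level values, discs are strongly clustered
within subjects: the trend test's nominal variance understates seed-to-seed
spread, so grade-shift tests assert the directional property rather than
uniform rejection at extreme α. Voxel tables (225 NP voxels per disc,
~146k total) are centred and scaled so each disc's voxel mean/SD equals its
record exactly, with per-grade voxel SDs {18, 15, 10, 8, 6} ms shrinking as
degeneration advances; paired T2 voxel values carry a planted squared
correlation of 0.80 via `T2 = −0.3 + 0.857·T1ρ + ε` with ε scaled to the
realised T1ρ variance.

What the generator does **not** emulate: spatial anatomy of real spines,
partial-volume and chemical-shift artifacts, Rician bias at low SNR (a
Rician option exists for the phantom), radiologist grading behaviour,
longitudinal change, or any dependence of BMI/ODI/VAS on disc state. Tests
passing on this generator therefore validate the computational machinery
and its statistical calibration — not clinical claims about real cohorts.

## The digital phantom

`generate_phantom()` builds five elliptical discs (semi-axes 16 × 6 voxels)
on four mid-sagittal slices, each with an NP core occupying the central 40%
of the AP extent (planted T1ρ 85 ms NP / 55 ms annulus; T2 65 / 45 ms),
amplitude 1000 and Gaussian magnitude noise at SNR 50, optionally rotated
in-plane for invariance studies. Signals are clipped at zero as magnitude
images are non-negative. Ground-truth maps and masks ship alongside the
series, standing in for the scanner and the external segmentation network.

## Problem sizes and determinism

Every stochastic stage takes an explicit seed and is exactly reproducible;
pipeline artifacts embed the seed and a config hash. The package's own
verification uses sizes chosen to give tight Monte-Carlo error at desk
scale: 200 replicate cohorts for recovery and CI-coverage studies
(Monte-Carlo SE of a 200-seed mean ≈ sampling SD / 14), 100 random series
for the grid-oracle comparison, 50,000 voxel pairs for the planted-R²
check, and ~6,000-voxel phantoms for the imaging chain.

## Known limitations

* Mono-exponential decay only; no multi-exponential or stretched models,
  no B0/B1 correction, and series are assumed co-registered.
* Wald inference throughout (no Satterthwaite degrees of freedom, no
  bootstrap); with 133 subjects the difference is small but real.
* The exact contrast construction of other statistical software differs in
  detail; small numeric differences in reported contrasts are expected.
* In-plane (sagittal) standardisation only; no left-right axis handling and
  no annulus sub-regions.
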