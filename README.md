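# nprelax

Quantitative MRI relaxometry and cohort statistics for lumbar
intervertebral disc degeneration.

Degenerating discs lose proteoglycan and water long before structural
damage is visible on conventional T2-weighted MRI. Spin-lock (T1ρ)
relaxation times measure that biochemical state directly, and the mean T1ρ
in the nucleus pulposus (NP-T1ρ) of each disc is a continuous biomarker of
disc health. `nprelax` is for imaging scientists and biostatisticians who
need the full pathway from raw multi-spin-lock image stacks to cohort-level
inference — and a synthetic ground truth to verify every step of it.

The package implements:

* **Relaxometry** — voxel-wise fits of the mono-exponential decay
  `SI(TSL) = S0 · exp(−TSL / T1ρ)` across spin-lock times (T2 analogously),
  by variable projection: the amplitude is profiled out in closed form and
  the relaxation time found by a global 1-D search within a clamp
  `[1, 500]` ms. Background masking, validity flags, NIfTI in/out.
* **Disc geometry** — each disc mask is rotated into the principal frame of
  its rotational inertia tensor (second-moment matrix of voxel
  coordinates); the NP is the central anterior–posterior 40% of the disc's
  extent in that frame. No intensity resampling ever occurs.
* **Biomarkers** — per-disc NP mean ± SD, whole-disc mean, valid-voxel
  accounting, voxel-level export.
* **Cohort statistics** — a random-intercept mixed model with the full
  age × sex × level × group factorial (REML, Wald inference), level-wise
  OLS with an age × group interaction, marginal slopes/contrasts derived by
  averaging over the observed covariate distribution, predictions,
  Pearson correlations, Student's t / chi-square / Cochran–Armitage trend
  tests, Pfirrmann-grade voxel histograms and the voxel-wise T1ρ–T2 R².
* **Synthetic data** — a phantom generator (known relaxation maps, SNR
  control, optional rotation) and a cohort generator calibrated so that the
  planted design — 133 subjects, 650 discs, level-specific means, a
  −1.0 ms/yr age slope flattening to −0.3 ms/yr in the cLBP group at L5–S1,
  an 8.1 ms sex gap, an 11.3 ms L5–S1 group gap — is recoverable by the
  statistical machinery.

## Worked example

Simulate the default synthetic cohort and run the core models:

```r
library(nprelax)

co <- generate_cohort()                  # deterministic: seed 20230101
#> <disc_cohort> 133 subjects, 650 disc records, 146250 NP voxels (seed 20230101)

m <- fit_mixed_model(co$discs)
marginal_effects(m)
#>                   quantity estimate    se  ci_lo  ci_hi        p
#> 1                age_slope    -1.09 0.115 -1.313 -0.863 2.29e-21
#> 2    sex_male_minus_female     3.33 2.836 -2.232  8.883 2.41e-01
#> 3 group_control_minus_clbp     6.47 2.921  0.747 12.199 2.67e-02
```

NP-T1ρ declines by about 1.1 ms per year of age in this realisation
(marginal, observation-weighted over all 650 discs), males run a few ms
higher than females at a given age, and controls a few ms higher than cLBP
patients overall. The level-wise L5–S1 model turns those into age-specific
reference values:

```r
lw <- fit_levelwise_model(co$discs, "L5S1")
predict(lw, data.frame(age = c(30, 50, 50),
                       group = c("control", "cLBP", "control")))
#>     fit    se ci_lo ci_hi
#> 1 88.17 4.638 79.08 97.26   # asymptomatic, age 30
#> 2 56.35 2.433 51.58 61.12   # cLBP, age 50
#> 3 64.48 3.196 58.22 70.75   # asymptomatic, age 50
```

— an NP-T1ρ of 60 ms would be highly atypical for an asymptomatic
30-year-old but unremarkable at 50. The voxel export carries a planted
T1ρ–T2 relationship:

```r
voxelwise_t1r_t2_correlation(co$voxels$t1rho_ms, co$voxels$t2_ms)$r2
#> [1] 0.799
```

The imaging chain runs the same way on a phantom with known truth
(NP planted at 85 ms, annulus at 55 ms, SNR 50):

```r
ph <- generate_phantom()
res <- image_pipeline(list(T1rho = ph$series_t1rho), ph$segmentation,
                      config = relax_config(noise_sigma = ph$spec$sigma))
res$discs[, c("level", "np_mean", "np_sd", "n_valid_voxels")]
#>   level np_mean np_sd n_valid_voxels
#> 1  L1L2   85.36 5.066            580
#> 2  L2L3   85.19 4.688            580
#> 3  L3L4   85.11 4.831            580
#> 4  L4L5   84.77 4.908            580
#> 5  L5S1   85.53 5.021            580
```

`run_pipeline(run_config(out_dir = "out"))` composes everything —
simulate, fit, extract, aggregate, analyze — and writes NIfTI maps, CSV
tables and a JSON report whose seed and config hash make reruns
byte-identical. A thin command-line wrapper with `simulate`, `fit-map`,
`extract-roi`, `analyze` and `run-all` subcommands ships in
`inst/cli/nprelax.R`.

## Documentation

The methods vignette (`vignettes/disc-relaxometry-methods.Rmd`) documents
the decay model and fitter, the inertia-tensor NP extraction, the model
coding and marginal-effect construction, the generator's calibration and
variance budget, what the synthetic data does and does not emulate, and
known limitations.
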