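# gradosc

Gray-matter atrophy in dementia reshapes whole-brain functional
connectivity (FC), but the link is hard to see edge by edge: 30,135
region pairs move together in a handful of coordinated patterns.
`gradosc` implements an analysis chain that explains those patterns
through the dynamics of a few **activity gradients** — the leading
principal components of regional BOLD timeseries — and provides a
synthetic cohort generator with planted ground truth so that every
stage can be validated quantitatively without any imaging data.

The package is aimed at researchers analysing task-free fMRI in
neurodegenerative cohorts (or simulating such analyses), and at
methodologists who want a tested reference implementation of
gradient-space FC algebra and linear dynamical-system fitting for
region timeseries.

## What it computes

**Gradient space.** A normative pool of region timeseries is
concatenated and decomposed by PCA; the leading K eigenvectors (the
gradients, the first one unipolar) span a latent space. Any subject's
timeseries projects to gradient scores `G(t)`, and the subject's FC
follows from gradient second moments: with orthonormal basis `V` and
gradient covariance `Σ`, the region covariance is `V Σ Vᵀ`, which at
full rank reproduces direct Pearson FC exactly.

**Structure-function components.** Regional atrophy is expressed as
covariate-adjusted W-scores, `W = (predicted − actual) / SD`, oriented
so positive = atrophy. Partial least squares regression (NIPALS PLS2)
decomposes the subjects × regions atrophy matrix into components that
maximally covary with the subjects × edges FC matrix, with split-half
reliability, PCA-based atrophy scores, and leakage-free ridge
regression (α = 1000, stratified 4-fold CV) for out-of-fold function
scores.

**Oscillator model.** Each subject's gradient timeseries is modelled as
linear coupled damped harmonic oscillators: for each gradient k,

    G_k'' = β_k0 + Σ_j P_kj G_j + Σ_j D_kj G_j'

fitted by least squares on finite-difference derivatives. The
companion-form state matrix `A` (2K × 2K) is eigendecomposed into
modes `λ = α + iβ` (damping per TR, angular frequency rad/TR,
frequency `β/2π/TR` Hz) with complex per-gradient components. Closed
form and RK4 simulation of the system reproduce each subject's FC.

**Eigenmode metrics.** Each gradient's cumulative amplitude
(`√2 Σ_m |a + ib|`, excitation-weighted) and each pair's
amplitude-weighted circular-mean phase angle summarise the fitted
dynamics; departures of angles from 90° ("phase collapse") and
amplitude loss map onto the gradient covariance and variance changes
that drive FC alterations.

**Synthetic cohorts.** `synth_config()` + `make_cohort()` plant all of
the above: known eigenstructure (frequencies, damping, pairwise phase
targets), severity-dependent G1 amplitude loss and G1–G4 phase
collapse, atrophy maps built from a global-severity pattern plus focal
patterns, and behavior scores linear in the planted factors.

## Worked example

```r
library(gradosc)

cfg <- synth_config(n_subjects = 16, n_regions = 24,
                    n_gradients = 4, n_timepoints = 140, seed = 7)
report <- run_pipeline(cfg, out_dir = "demo_out", n_trials = 2)
#> [gradosc] generating cohort (seed 7)
#> [gradosc] QC: framewise displacement filter at 0.55 mm
#> [gradosc] 0 scan(s) excluded for motion
#> [gradosc] computing per-subject FC
#> [gradosc] 2 scan(s) flagged as FC outliers
#> [gradosc] 14 of 16 scans analyzed
#> [gradosc] fitting gradient basis on 5 normative scans
#> [gradosc] projecting cohort and fitting oscillator models
#> [gradosc] PLSR structure-function components
#> [gradosc] cross-validated ridge function scores

report$plsr
#> Structure-function components (PLSR): 3 components
#> Atrophy variance explained: 49.9% 36.0% 5.2%
#> Structure-function score correlation: 0.62 0.46 0.77
```

The first two PLSR components absorb most of the atrophy variance —
the planted cohort mixes a global-severity pattern with focal
patterns, and at this small demonstration size the focal factors carry
a substantial share. Structure and function scores correlate because
the generator couples severity to the gradient dynamics that produce
FC. The output directory holds
`scores.csv` (per-subject structure and function scores with
covariates, ready for downstream behavioural models), per-subject
eigenmode metrics and gradient moments, the metric/moment correlation
table, the QC exclusion list, and `summary.json` stamped with the seed
and a configuration hash — rerunning with the same seed reproduces it
byte for byte.

Fitting a single subject's dynamics directly:

```r
sub <- simulate_oscillator_subject(cfg, severity = 1.5, seed = 11)
fit <- fit_oscillator(sub$true_gradient_timeseries)
summary(fit)          # coupling R^2 and the eigenmode table
eigen_metrics(fit)    # cumulative amplitudes and pairwise angles
```

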