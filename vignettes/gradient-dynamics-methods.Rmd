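---
title: "Gradient dynamics and structure-function coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient dynamics and structure-function coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradosc)
```

This vignette describes the models implemented in `gradosc`, the
assumptions behind them, the synthetic study conditions used to
validate them, and the numerical choices a user should know about.

## 1. The gradient latent space

Resting-state BOLD activity across hundreds of regions is strongly
low-dimensional. `fit_gradient_basis()` concatenates a normative pool
of region timeseries (rows: timepoints, columns: regions), centers
each region, and performs PCA. The leading K eigenvectors are the
*gradients*: spatial maps whose time-varying scores describe the main
axes of whole-brain activity. The first gradient is typically
unipolar — every region weighted with the same sign — so its score
tracks the global signal; `global_signal_amplitude()` makes that
relation explicit.

Two conventions matter:

* **Projection uses the orthonormal eigenvectors.** Loadings scaled by
  the (square-root) eigenvalue are kept only for display
  (`display_loadings`). All covariance algebra requires orthonormal
  columns, and the scaling cancels in correlations anyway.
* **Signs.** PCA signs are arbitrary; each eigenvector is flipped so
  its largest-magnitude region weight is positive. The same convention
  is used for PCA and PLSR loadings, making reruns reproducible.

FC follows from gradient second moments. For orthonormal basis
$V \in \mathbb{R}^{R\times K}$ and per-subject gradient covariance
$\Sigma = \mathrm{cov}(G)$ (unbiased, $n-1$ denominator everywhere),

$$\mathrm{cov}(\text{regions}) = V\,\Sigma\,V^\top,$$

and Pearson correlations follow from its diagonal. With $K = R$ this
equals direct Pearson FC to machine precision (tested on random
inputs); with small K it is the rank-K account of FC that the rest of
the package studies. Regions with zero implied variance are reported
as `NA` and flagged, never silently zeroed. Edge vectors use the
row-major upper triangle without the diagonal ($R(R-1)/2$ entries;
30,135 at $R=246$), covariance flattening includes the diagonal
(30,381). Gradient scores enter covariances unstandardized; a
correlation-based variant of the pairwise moments exists for the
metric-correspondence analysis (section 5).

`variance_partition()` attributes across-subject variance of an FC
summary score to the 21 gradient moments (6 variances, 15
covariances) by multiple regression. Because the paper-style question
("how much of this score is gradient-1 variance?") has no unique
answer under correlated predictors, the share of each term is the
average of its sequential sum of squares over 200 random predictor
orderings (LMG-style hierarchical partitioning), which is symmetric,
non-negative, and sums to the model $R^2$. Near-collinear moment
tables trigger a warning and a ridge-stabilised fallback for the
t-statistics.

## 2. Atrophy W-scores and structure-function components

`fit_wscore_model()` regresses each region's gray-matter value on
covariates in a reference sample; `apply_wscores()` scores new
subjects as

$$W = \frac{\text{predicted} - \text{actual}}{\text{residual SD}},$$

so positive W means *more atrophy than expected*. The raw
deficit-negative form is available via a flag, but every downstream
use in the package assumes atrophy-positive orientation.

`fit_plsr_components()` implements NIPALS PLS2 with deflation.
Atrophy is the X ("grounding") side; FC edges are Y. Columns are
centered but not variance-scaled: W-scores and FC edges already live
on comparable scales, and unit-scaling 30,135 noisy edges would
up-weight the noisiest ones. A `scale.` flag restores the scaled
variant. Per component the object records structure loadings (region
space), function loadings (edge space), paired subject scores, their
correlation, and the fraction of atrophy variance explained.

Supporting machinery:

* `split_half_reliability()` repeats PLSR in label-balanced half
  cohorts. Because component order and sign can swap between fits,
  half-2 components are matched to half-1 by greedy maximum-|r|
  assignment before the absolute loading correlation is recorded.
* `atrophy_pca_scores()` provides atrophy-only component scores for
  cross-validation, avoiding the contamination that PLSR scores (which
  have seen FC) would introduce.
* `ridge_function_scores()` ridge-regresses each atrophy component on
  all FC edges with stratified k-fold CV (defaults: $\alpha = 1000$,
  4 folds, 20 refold trials). A subject's function score comes only
  from folds where the subject was held out, so structure and
  function scores are decorrelated by construction; shuffling the
  test-fold rows drives the out-of-fold correlation to zero (tested).
  The ridge solve uses the SVD of the centered training matrix with an
  unpenalised intercept.
* `reconstruct_fc_from_components()`, `network_summary_map()`,
  `mds_embed()` and `typical_patients_lda()` provide the standard
  readouts (low-rank FC reconstruction, region-wise edge-weight sums,
  2-D embedding of subjects, LDA-based "typical pattern" flags with a
  regularized fallback when the within-class scatter is singular).

## 3. The coupled damped harmonic-oscillator model

For K gradient timeseries $G$ with derivatives $G'$, $G''$ (time unit
= 1 TR), each gradient's acceleration is modelled as a linear function
of all positions and velocities:

$$G''_k = \beta_{k0} + \sum_j P_{kj} G_j + \sum_j D_{kj} G'_j .$$

`fit_oscillator()` estimates the $2K+1$ coefficients per equation by
least squares. Derivatives come from `finite_difference_derivatives()`:
central first differences with one-sided endpoints, and the *direct*
central second difference $G_{t+1} - 2G_t + G_{t-1}$. The direct form
is exact for quadratics over the whole interior and attenuates an
oscillation of frequency $\omega$ rad/TR by only
$1 - \omega^2/12$, whereas iterating the first-difference operator
twice attenuates by $\mathrm{sinc}^2(\omega) \approx 1 - \omega^2/3$ —
an 8% coefficient bias at $\omega = 0.5$ that would defeat parameter
recovery.

Endpoint rows (whose derivative estimates are one-sided) are kept in
the regression by default. For noiseless decaying trajectories the
first row carries both the largest amplitude and the largest
derivative error and can dominate the fit, so
`endpoint_rows = "drop"` removes the two endpoint rows; the recovery
analyses use that option.

The second-order system is rewritten as $dY/dt = AY + b$ with the
state $Y = (G, G')$ and the companion matrix

$$A = \begin{pmatrix} 0 & I \\ P & D \end{pmatrix},$$

whose upper blocks are exactly $[0\,|\,I]$ (asserted). Intercepts form
an affine offset; simulation operates on deviations from the fixed
point $-A^{-1}b$ and adds it back.

`compute_eigenmodes()` eigendecomposes $A$. Conjugate pairs collapse
to one mode each (representative with $\beta \ge 0$); purely real
eigenvalues are retained as overdamped modes. Frequencies are reported
in Hz as $\beta / 2\pi / \mathrm{TR}$ — all fitting stays in TR units
and the conversion happens only at reporting, so mixed-TR cohorts are
handled per subject without resampling. Gauge: each mode's position
subvector is normalized to unit modulus-norm and rotated so gradient
1's component has phase zero (largest-amplitude gradient as fallback);
all pairwise phase differences are invariant to this choice (tested
with random rotations). Near-degenerate eigenvector matrices
(condition number above $10^8$) are flagged rather than silently
used; the trace identity $\sum \lambda = \mathrm{tr}(A)$ is checked on
every decomposition.

`simulate_gradients()` evolves the system either in closed form,
$Y(t) = \Re\{V e^{\Lambda t} V^{-1} Y_0\}$, or numerically (RK4 via
`deSolve`, 20 substeps per TR); the two agree to $<10^{-6}$ over 500
steps on stable systems and an overflow guard refuses long horizons on
unstable fits. `simulate_subject_fc()` closes the loop: fit →
eigenmodes → simulate → mix to regions through the basis → FC. The
ensemble mode launches one trajectory per observed timepoint (each
running the scan length) and averages the FC matrices; the single
mode uses the first state only. The two agree closely on stationary
data; on decaying deterministic data the ensemble mixes window effects
and the single mode is the exact self-consistency check. Unstable
fits fall back to a recorded single short-horizon simulation.

## 4. Eigenmode amplitudes and phase collapse

Per mode $m$ and gradient $g$ with complex component $a + ib$, the
amplitude term follows the solution form,
$\sqrt{(b-a)^2 + (a+b)^2} = \sqrt{2}\,|a+ib|$, and the cumulative
amplitude sums it over modes. Two weighting conventions exist and the
distinction matters:

* **Excitation weighting (default in `eigen_metrics()`).** The
  observed states are expressed in the eigenbasis,
  $c(t) = V^{-1} Y(t)$, and each mode's component is scaled by the RMS
  of $|c_m(t)|$. The products $|c_m||v_m[g]|$ are invariant to the
  arbitrary per-mode eigenvector scale, and the resulting cumulative
  amplitude is *exactly* homogeneous: multiplying a gradient's data by
  $\lambda$ multiplies its amplitude by $\lambda$. Any purely
  eigenvector-based normalization breaks this homogeneity, because
  rescaling one gradient changes every mode's norm.
* **Gauge amplitudes** ($|v_m[g]|$ in the fixed gauge) describe the
  system's mixing structure irrespective of how strongly modes are
  driven; they are the weights used for phase angles.

The pairwise phase angle of gradients $(i, j)$ is the circular mean of
the per-mode angle differences $\arg(v_m[i]) - \arg(v_m[j])$, each
wrapped to $(-180, 180]$ first, weighted by the product of the two
gradients' gauge amplitudes on that mode (normalized per subject).
Overdamped modes participate with their real components. Excitation
reweighting is deliberately *not* used here: a coupled pair's phase
information lives in the balance of its two shared modes, and
excitation weights distort that balance.

Ninety degrees means temporal orthogonality; systematic departures
("phase collapse") make the pair's timeseries correlate as
$\cos(\text{angle})$ — an identity that holds exactly for a single
shared mode over whole cycles and is verified to 0.05 in the tests.
Because the covariance of two gradients depends on the *cosine* of
their angle, an even function, second moments cannot identify the
sign of an angle; across-subject comparisons against covariance
moments therefore use the absolute angle
(`eigen_metrics(angle_convention = "absolute")`). Signed angles remain
the default report.

`metrics_variance_correlation()` assembles the 21 × 21 table of
metric-moment correlations (amplitudes and angles against variances
and pairwise moments, identically ordered) and summarises the
corresponding (diagonal) versus non-corresponding entries.

## 5. The synthetic study conditions

The generator's purpose is to plant *known* dynamical structure that
the analysis chain must recover. Its defaults were chosen once, as
follows, and define the conditions under which the validation suite
runs.

**System construction.** Rather than drawing random coefficient
matrices (whose phase geometry is uncontrolled and often
near-degenerate), `plant_oscillator_system()` specifies the
eigenstructure directly: mode $m$ gets eigenvalue
$\alpha_m + i\beta_m$ and a position eigenvector with component 1 on
gradient $m$ and cross components of magnitude $\varepsilon$ on the
others, whose phases encode the target pairwise angles coherently on
both shared modes of every pair. The real coefficient blocks follow
from solving $[P\ D]\,[\Re M | \Im M] = [\Re(U\Lambda^2) |
\Im(U\Lambda^2)]$ with $M = (U; U\Lambda)$. Stability is guaranteed by
choosing $\alpha < 0$. Because dense cross components let every mode
contribute to every pair's circular mean, the working phases are
calibrated jointly (damped fixed-point iteration) until each pair's
achieved amplitude-weighted angle equals its target to 0.01°. An
earlier design that planted phase collapse through a single
off-diagonal position coupling was abandoned: such a coupling splits
the pair into in-phase and anti-phase normal modes of nearly equal
weight, and the circular mean of two antipodal contributions is the
direction of a near-cancelling resultant — unstable to estimate and
unusable as ground truth.

**Default parameters and why.** Eigenfrequencies are evenly spaced
over 0.15–0.47 rad/TR (0.012–0.037 Hz at TR = 2 s, inside the usual
0.008–0.08 Hz band); even spacing matters because eigenvector
estimates degrade as the inverse frequency gap, and near-degenerate
pairs are unrecoverable. Damping ratio 0.05 keeps the oscillators
narrow-band (smooth series, precise coefficient estimates) while
leaving the moments estimable at the run lengths used. Cross-component
magnitude 0.3 makes every gradient participate in every mode at a
level well above estimation noise. Pairwise phase targets are drawn
from $\mathcal{N}(90°, 30°)$ clipped to [30°, 150°]; per-gradient
output gains are lognormal (SD 0.25); per-subject frequency jitter is
1%.

**Severity effects.** Severity $s$ multiplies gradient 1's output by
$1 - 0.25\,s$ (so expected G1 variance falls by the squared factor,
verified against a Monte-Carlo oracle) and moves the gradient-1/4
phase target to $90° - 15°\,s$. Atrophy maps are
$s\,g + f_2 p_2 + f_3 p_3 + \text{noise}$ with an all-positive
global pattern $g$ (per-region contrast $|\mathcal{N}(1, 0.4)|$,
normalized) and focal patterns orthogonal to both $g$ and the
constant vector, so focal factors leave mean atrophy untouched.
Behavior scores are fixed linear combinations of $(s, f_2, f_3)$ plus
noise.

**Forcing.** The fitted model is deterministic, but generating
stationary series requires a drive; subjects are integrated as the
same linear system under white-noise forcing on the velocity
equations (Euler–Maruyama, inner step TR/10, 200 TR burn-in
discarded). Fitting the deterministic regression to noise-driven
trajectories is exactly the estimation problem faced on real data.
The white-noise choice is an assumption — nothing is known about the
true forcing of gradient dynamics — and is recorded in the
configuration. Real BOLD features the generator deliberately omits:
hemodynamic convolution, scanner drift and motion artefacts,
bandpass-filter autocorrelation, and non-stationarity. Passing tests
therefore show the *estimators* are correct and well-calibrated under
the model's own assumptions, not that real data satisfy them.

**Problem sizes in the validation suite.** Parameter recovery uses
deterministic fine-step trajectories of 2,000 TRs (coefficient errors
< 5%, eigenfrequencies < 2%, damping < 10%). Phase and amplitude
recovery use deterministic dominant-mode and scaled trajectories,
where recovery is exact up to discretization. The PLSR/ridge analyses
use a 300-subject, 100-region planted cohort with 200 split-half
replicates. The metric-moment correspondence uses 100 noise-driven
subjects at 4,000 TRs with continuous severities: at realistic scan
lengths the sampling error of a light-damped oscillator's covariance
(effective sample size $\approx T \cdot \text{damping}$) would mask
the planted effects, so the validation lengthens the runs rather than
distorting the dynamics. The generator's scan-length default for
pipeline demonstrations remains 235 TRs.

## 6. Quality control and pipeline

`qc_fd_filter()` excludes scans whose mean framewise displacement
exceeds 0.55 mm. `qc_fc_pca_outliers()` stacks flattened FC vectors,
takes the first principal component, and flags scores more than one
SD above the mean; the component is oriented by the skewness of its
scores so the flag does not depend on PCA sign or row order.
`run_pipeline()` chains QC → normative-pool basis → projection → FC →
PLSR + atrophy PCA + ridge → oscillator fits → eigenmode metrics →
metric/moment correlation, records a reason for every exclusion
(counts reconcile by construction), and stamps all outputs with the
seed and a configuration hash so reruns are byte-identical.

## 7. Known limitations

* The least-squares fit of the continuous-time model on discretely
  sampled, stochastically forced data is biased for heavy damping
  (the forcing roughness contaminates the finite differences); the
  package targets the light-damping, band-limited regime of gradient
  timeseries.
* Generalized (defective) eigenvectors are not handled; near-repeated
  eigenvalues are flagged by condition number and such fits should be
  excluded rather than interpreted.
* Signed phase angles near 0° or 180° are fragile across refits (the
  circular resultant can flip); the absolute-angle convention is the
  robust cohort-level quantity.
* ComBat-style site harmonization and behavioural (GAM/mixed-effects)
  modelling are out of scope: the pipeline exports tidy score tables
  with covariates for external tools.
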