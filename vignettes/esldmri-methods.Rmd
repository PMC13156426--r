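---
title: "Methods: ESL decomposition and compartment modelling of multidimensional dMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ESL decomposition and compartment modelling of multidimensional dMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions, parameter choices and
numerical decisions behind `esldmri`. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The tissue model

Prostate tissue is described by three components: epithelium (gland-lining
cells), stroma (fibromuscular connective tissue) and lumen (fluid-filled
glandular space). The central assumption of the framework is *linearity of
partial-volume mixing*: the normalised dMRI signal of a low-resolution
voxel is the volume-fraction-weighted sum of per-component signals,

$$S(b_i, \Delta_i) = f_E\,S_E(b_i, \Delta_i) + f_S\,S_S(b_i, \Delta_i)
  + f_L\,S_L(b_i),$$

with the fractions measured independently at 20 μm from MR microscopy.
The luminal signal is not estimated but fixed to free diffusion at
2.0 μm²/ms — the diffusivity of the surrounding medium — on the grounds
that luminal fluid equilibrates with the medium in small fixed samples
immersed for more than a day. Fixing it removes one column from the
per-sequence regression and reduces the variance of the epithelial and
stromal estimates.

Aggregate component signals are estimated *per sequence* by ordinary
least squares of the lumen-corrected signal on $(f_E, f_S)$, pooling all
benign voxels. This treats each component's signal as common across
voxels and samples; departures from that assumption appear as residual
variation, which the limits-of-differences machinery is designed to
quantify rather than hide. The OLS is deliberately unconstrained:
negative aggregate estimates are a diagnostic of misfit and are reported
with a warning, never clipped.

### Units

All internal quantities use b in ms/μm² (1000 s/mm² ≡ 1.0 ms/μm²),
times in ms, lengths in μm and diffusivities in μm²/ms, keeping every
fitted parameter near unit magnitude and the least-squares problems well
conditioned. Converters (`b_to_internal()`, `diffusivity_to_internal()`)
live at the I/O boundary; thresholds quoted in mm²/s (such as the
stroma cutoff 1.4 × 10⁻⁴ mm²/s ≡ 0.14 μm²/ms) are converted on entry.

## Segmentation

The 20 μm label map is built from thresholds:

* **Lumen/fluid** — voxels of the echo-averaged gradient-echo image at or
  above `lumen_threshold_value × median(medium intensities)`. The
  reference statistic is the median of a user-supplied medium region (in
  the phantom pipeline, a ring between the tissue core and the tube
  wall); the multiplier defaults to 0.8. The source protocol states only
  that the threshold was derived from medium intensities, so the
  statistic and multiplier are explicit configuration surfaced in the
  `threshold_sensitivity()` sweep.
* **Air / unclassified** — voxels below an absolute floor
  (`air_min_threshold`, default 0.2 on the phantom's intensity scale),
  removing signal voids such as air bubbles.
* **Stroma** — voxels whose product of mean diffusivity and fractional
  anisotropy exceeds 0.14 μm²/ms. "D" is taken to be the tensor's mean
  diffusivity (MD); the tensor is fit by unweighted log-linear least
  squares (seven unknowns per voxel), exact on noiseless signals, with
  negative eigenvalues clamped to zero before MD and FA. Denoising and
  upsampling (40 → 20 μm voxel-centre trilinear interpolation) precede
  the tensor fit, matching the stated processing order.
* **Epithelium** — everything else inside the region of interest, with
  precedence lumen/air → stroma → epithelium.

Volume fractions per low-resolution voxel are exact label counts
(480 × 480 × 320 μm³ voxels contain 24 × 24 × 16 = 9216 microscopy
voxels). Voxels with unclassified fraction below 0.05 are kept with
(f_E, f_S, f_L) renormalised; above that they are excluded — the
configurable cutoff reflects that unclassified volume averaged well
under 1% in the data the method was developed on.

## Diffusion signal models

Four models are fit to 10-point signal profiles (five b-values × two
diffusion times):

* ADC: $S_0 e^{-bD}$
* Kurtosis: $S_0 e^{-bD + \frac{1}{6}K b^2 D^2}$
* Sphere: $S_0\,E_{sph}(b, \delta, \Delta; R, D)$
* Ball+Sphere: $S_0\big(f_{sphere} E_{sph}(b, \delta, \Delta; R,
  D_{sphere}) + (1 - f_{sphere})\,e^{-b D_{ball}}\big)$

$E_{sph}$ is the Murday–Cotts closed form for diffusion inside
impermeable spheres under the Gaussian phase distribution approximation,
summed over the eigenmodes $\alpha_m = x_m / R$ where $x_m$ are roots of
$j_1'(x) = 0$. Numerical choices:

* the series is truncated at 50 roots; 20 terms leave errors up to
  ~3 × 10⁻⁵ at the corner of the protocol's parameter range (large R,
  small D, short Δ) whereas 50 keep the worst case near 3 × 10⁻⁷
  against a 200-term evaluation, at negligible cost since the sum is
  vectorised. The relative size of the last term is returned as an
  attribute for diagnostics;
* roots are bracketed by a sign scan of
  $(x^2 - 2)\sin x + 2x\cos x$ and refined to ~10⁻¹³, then cached;
* $D = 0$ returns attenuation 1 exactly (no motion, no dephasing);
* the gradient factor is recovered from the b-value via the standard
  pulsed-gradient relation $b = (\gamma g \delta)^2 (\Delta -
  \delta/3)$; the stimulated-echo pair is treated as a pulsed-gradient
  pair with the nominal (δ, Δ), relaxation during mixing being removed
  by b = 0 normalisation.

### Fitting

All models are fit by bounded Levenberg–Marquardt least squares on the
signal (not the log-signal), from a fixed deterministic multi-start grid
(8 starts; the lowest-RSS solution wins). Bounds: S₀ ∈ [0.5, 1.5],
diffusivities ∈ [0.01, 3] μm²/ms, K ∈ [0, 5], R ∈ [0.5, 40] μm,
f_sphere ∈ [0, 1]. Two deliberate additions:

* models that nest ADC (kurtosis, Ball+Sphere) receive one extra start
  derived from a closed-form log-linear ADC fit, which guarantees in
  practice that the richer model never fits worse than its special case;
* `fit_voxelwise()` defaults to a 4-start subset of the grid for
  throughput over thousands of voxels; measured and predicted profiles
  always share starts so that optimizer idiosyncrasies cancel in the
  difference.

The Ball+Sphere volume fractions are constrained to sum to one
(f_ball = 1 − f_sphere, four free parameters plus S₀). With ten data
points, an independently floating f_ball and S₀ are not jointly
identifiable, and reported benign-tissue fits carry S₀ ≈ 1 with no
independent ball fraction.

AICc is computed as $n \ln(rss/n) + 2k' + 2k'(k'+1)/(n - k' - 1)$ with
$k' = k + 1$, counting the Gaussian residual-variance parameter — the
standard least-squares convention. The convention is configurable
(`count_variance = FALSE`) because model ranking, not absolute AICc,
is the quantity of interest. Parameter standard errors use first-order
error propagation, $\mathrm{SE} = \sqrt{\mathrm{diag}(\hat\sigma^2
(J^\top J)^{-1})}$ with $\hat\sigma^2 = rss/(n-k)$ and a
central-difference Jacobian; a rank-deficient $J^\top J$ falls back to a
pseudo-inverse with the result flagged unreliable. Perfect fits
(rss = 0) report AICc = −∞ rather than an error, which is the correct
ranking behaviour for noiseless round trips.

### Uncertainty of the aggregate estimates

Bootstrap resampling (default N = 10 000) resamples voxels — signal and
fractions together — and refits the two-parameter OLS per replicate;
standard errors are replicate SDs and 99% intervals the 0.5th–99.5th
percentiles. Replicates with a singular design are skipped and counted.
R² is reported for the full three-component prediction against the
mean of the lumen-corrected response — the conventional OLS baseline,
made explicit because the quantity depends on it.

## The voxelwise comparison

For every voxel, ADC and Ball+Sphere are fit to the measured profile and
to the profile predicted from the aggregate estimates and the voxel's
own fractions. The prediction is a composition-matched benign baseline,
so parameter differences isolate signal behaviour not explained by
composition. 95% limits of differences (mean ± 1.96 SD across benign
voxels, pooled, Bland–Altman style) define the benign variability band;
cancer voxels are then judged by the fraction of differences outside
those limits. Non-converged and bound-pegged fits are excluded from the
limits (boundary estimates distort SDs) but counted and reported.

## What the phantom emulates — and what it does not

`generate_phantom()` builds a cylindrical tissue core inside a
medium-filled tube: spherical lumens (radius 40–120 μm, matching benign
acinar dimensions) wrapped in epithelial shells (25–45 μm, one to two
cell layers; the resulting epithelium:lumen volume ratio of ~2:1 matches
reported benign fractions of ~28%/14%), packed into stroma until the
target gland density (default 0.42 of the tissue) is reached, with a
smooth random fiber orientation field in stroma. Component signal
behaviour: Ball+Sphere forward models with the published benign
epithelial and stromal parameter sets; free diffusion at 2.0 μm²/ms in
lumen and medium; axially symmetric stroma tensor (1.4, 0.6) μm²/ms for
the DTI contrast (FA 0.489, MD 0.867 μm²/ms).

Noise is Rician (magnitude of complex Gaussian), applied per direction
before any averaging. Two SNR knobs: `snr = 30` for the 20–40 μm
microscopy images, and `snr_dmri = 80` for the 160 μm dMRI series —
separate because the dMRI voxel volume is ~500× larger. The dMRI value
was chosen so that the Rician magnitude floor stays below the
highest-b fluid signal, consistent with the observation that high-b
measurements in fluid-dominated voxels show minimal Rician bias; no
Rician bias correction is applied anywhere in the pipeline, matching
the analysis it implements.

Per-sample heterogeneity (`sample_effect_sd`, default 0.13) draws, per
sample and tissue component, a flat multiplicative signal scale and a
common multiplier on the compartment diffusivities, both Gaussian
around 1. A flat scale alone cannot reproduce the reported residual
structure — it is absorbed almost entirely by S₀ in voxelwise fits —
whereas diffusivity heterogeneity is the natural physical reading of
sample-to-sample variation in fixed tissue (fixation time varied between
samples). The default was calibrated once so that a 14-sample benign
cohort reproduces per-sequence R² values inside the reported
0.563–0.737 range, and was not revisited afterwards.

The phantom does **not** emulate: k-space acquisition (no Gibbs
ringing — the analysis downsamples partly to suppress it in real data),
susceptibility effects, perfusion, realistic histological texture,
direction-dependent stroma signal in the STEAM series (the analysis
averages directions and treats anisotropy effects as small), or
intra-sample spatial heterogeneity of component properties. Passing
tests therefore validate the estimation machinery under the stated
model, not the biological fidelity of real prostate data.

## Characterized limitation: segmentation partial volume

With the default stroma tensor, pure-stroma D·FA (0.42 μm²/ms) sits 3×
above the 0.14 μm²/ms threshold, so 40 μm voxels containing roughly
half epithelium still exceed the cutoff after upsampling, and a
substantial minority of epithelial shell voxels are claimed as stroma.
The under-counted f_E inflates the extrapolated aggregate epithelial
profile, and the Ball+Sphere fit of that distorted profile can move to a
degenerate boundary representation (the model's sloppy directions
amplify ~0.01 profile changes into large parameter changes). The
pipeline therefore supports `fractions_source = "truth"`, which swaps in
the phantom's ground-truth labels: through that path aggregate
parameter recovery is tight (tested at ±0.03 on the epithelial sphere
fraction and ±0.05 μm²/ms on the stromal ball diffusivity), while the
threshold-segmentation path is tested at looser, characterized bounds.
This mirrors the acknowledged threshold sensitivity of gland/stroma
separation in the source protocol, and is the main reason learning-based
segmentation is flagged as future work there.

## Problem sizes and determinism

Tests and examples use phantoms from 48 × 48 × 64 up to
120 × 120 × 320 voxels at 20 μm (self-similar geometry: the tube
radius scales with the field of view), benign cohorts of 14 samples ×
18 voxels, and bootstrap sizes of a few hundred where the full 10 000
would add nothing to the property under test; these sizes were chosen so
the whole suite exercises every stage at laptop scale. Every stochastic
component is seed-driven: phantom construction, each simulator
(`seed + 1, 2, 3` for gradient echo, DTI and dMRI draws), cohort
generation and bootstrap resampling, so identical configurations yield
byte-identical outputs, and pipeline outputs are stamped with a
configuration hash and seed.
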