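# esldmri

Characterising the diffusion properties of prostate epithelium and stroma
from paired MR microscopy and multidimensional diffusion MRI (dMRI).

Prostate tissue is composed of three main components — epithelium, stroma
and lumen (ESL) — whose balance shifts with cancer grade. This package
implements an analysis framework for fixed-tissue samples imaged at two
scales: 20 μm MR microscopy, which resolves the components, and 160 μm
multidimensional dMRI (five b-values of 1.0–2.0 ms/μm², each at a short
and a long diffusion time Δ), which carries the diffusion information. The
framework

1. **segments** epithelium, stroma and lumen/fluid at 20 μm — bright
   (long-T2) voxels on the averaged gradient-echo image become
   lumen/fluid, voxels whose diffusivity-weighted fractional anisotropy
   exceeds `D·FA = 1.4 × 10⁻⁴ mm²/s` become stroma, and the remaining
   tissue is epithelium;
2. **decomposes** each low-resolution voxel signal as the linear mixture

   S(bᵢ, Δᵢ) = f_E·S_E(bᵢ, Δᵢ) + f_S·S_S(bᵢ, Δᵢ) + f_L·S_L(bᵢ),

   with volume fractions f from the segmentation and the luminal signal
   fixed at free diffusion (2.0 μm²/ms, the medium diffusivity), fitting
   per sequence by ordinary least squares to obtain aggregate epithelial
   and stromal signal profiles with bootstrap uncertainty (N = 10 000,
   99% percentile intervals);
3. **models** the aggregate profiles with four diffusion signal models —
   ADC (S₀·e^(−bD)), kurtosis (S₀·e^(−bD + Kb²D²/6)), Sphere
   (restricted diffusion in impermeable spheres via the Murday–Cotts
   expression under the Gaussian phase distribution approximation) and
   Ball+Sphere (f_sphere·Sphere(b,δ,Δ;R,D_sphere) +
   (1−f_sphere)·e^(−bD_ball)) — ranked by the small-sample corrected
   Akaike information criterion (AICc), with first-order error
   propagation for parameter standard errors;
4. **compares voxels against their composition-matched prediction**:
   ADC and Ball+Sphere are fit per voxel to both the measured profile and
   the profile predicted from the aggregate estimates, and 95% limits of
   parameter differences (mean ± 1.96 SD, Bland–Altman style) computed in
   benign tissue provide the yardstick against which cancer voxels are
   evaluated.

Because the source imaging data are not publicly deposited, the package
includes a first-class synthetic phantom generator
(`generate_phantom()`, `simulate_gre()`, `simulate_dti()`,
`simulate_dmri()`, `simulate_voxel_cohort()`) that reproduces the
statistical structure the analysis assumes: glandular geometry with
epithelial shells around lumens in anisotropic stroma, gradient-echo
contrast, Rician magnitude noise, and per-sample heterogeneity of
component diffusion properties.

## Worked example

Fit all four models to a noisy epithelium-like profile over the canonical
10-sequence protocol:

```r
library(esldmri)

seqs <- steam_sequences()                 # 10 (b, δ, Δ) combinations
prof <- model_forward("ballsphere",
                      reference_params("ballsphere", "epithelium"), seqs)
set.seed(1)
noisy <- prof + rnorm(10, 0, 0.002)
fit_model(noisy, seqs, "ballsphere")
#> Diffusion model fit: ballsphere
#>          estimate     se at_bound
#> S0         1.0020 0.0178    FALSE
#> f_sphere   0.2719 0.0205    FALSE
#> D_sphere   0.7215 0.0998    FALSE
#> R          6.2730 0.4060    FALSE
#> D_ball     0.6093 0.0525    FALSE
#>   RSS = 1.289e-05  n = 10  AICc = -95.62
```

The fitted sphere fraction (0.27), radius (6.3 μm) and ball diffusivity
(0.61 μm²/ms) recover the generating epithelial values; the AICc (−95.6)
beats ADC (−67.4), kurtosis (−61.7) and Sphere (−86.2) on the same
profile, the ordering expected when a restricted and a free compartment
are both present. On noiseless profiles the round trip is exact to
machine precision.

The whole pipeline — phantom, microscopy simulation, segmentation,
preprocessing (MP-PCA denoising, direction averaging, 3×3×2 block
downsampling, b = 0 normalisation, cylindrical ROI), decomposition,
model fitting and the voxelwise comparison — runs from one call:

```r
cfg <- pipeline_config(
  phantom = phantom_config(grid_shape = c(96, 96, 128), seed = 1),
  out_dir = "out")
res <- run_pipeline(cfg, verbose = TRUE)
res$aggregate_fits        # Table of parameters, SEs, RSS and AICc
res$parameter_limits      # 95% limits of parameter differences
```

A thin command-line wrapper is provided at
`inst/scripts/esldmri-cli.R` (`run` and `simulate` verbs).

## Scope and limitations

The segmentation is deliberately simple (fixed thresholds per sample
set, as in the source protocol); partial-volume effects at the 40 μm DTI
resolution bias epithelium/stroma assignment near gland boundaries, and
the methods vignette (`vignettes/esldmri-methods.Rmd`) quantifies what
this does to downstream estimates. Rician bias is not corrected
anywhere, matching the analysis the package implements. Acquisition
simulation (k-space, ringing, susceptibility) is out of scope.
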