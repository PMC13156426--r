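# Synthetic glandular phantom: paired MR-microscopy and multidimensional
# dMRI datasets with the statistical structure the analysis assumes.
#
# Label coding shared across the package:
#   1 = epithelium, 2 = stroma, 3 = lumen, 4 = medium, 5 = air.

#' Label levels used by phantoms and segmentations
#' @export
esl_labels <- function() {
  c(epithelium = 1L, stroma = 2L, lumen = 3L, medium = 4L, air = 5L)
}

#' Configuration for the synthetic phantom
#'
#' Defaults emulate one fixed-tissue sample: a ~3 mm tissue core inside a
#' medium-filled tube imaged at 20 um, with glandular lumens wrapped in
#' epithelial shells embedded in anisotropic stroma. Component dMRI
#' behaviour follows [reference_params()] (ball+sphere for epithelium and
#' stroma) with free diffusion at 2.0 um^2/ms in lumen and medium.
#'
#' @param grid_shape 3D voxel counts at microscopy resolution. The default
#'   240 x 240 x 320 is one full sample; tests use sizes down to
#'   48 x 48 x 64.
#' @param voxel_um microscopy voxel edge (um).
#' @param gland_density target lumen + epithelium fraction of the tissue
#'   cylinder.
#' @param lumen_radius_range,epithelium_shell_range gland geometry (um).
#' @param stroma_lambda axial and radial stroma tensor eigenvalues
#'   (um^2/ms); the defaults give FA 0.489, MD 0.867 so that the
#'   diffusivity-weighted anisotropy D*FA clears the 0.14 um^2/ms stroma
#'   threshold with a wide margin.
#' @param epithelium_d,lumen_d isotropic diffusivities for the DTI forward
#'   model (um^2/ms); lumen/medium default 2.0, the medium diffusivity.
#' @param component_params per-component dMRI forward parameters: list with
#'   `epithelium`, `stroma` (ball+sphere vectors) and `lumen_d`.
#' @param gre_intensities mean gradient-echo intensities per component
#'   (bright fluid, darker tissue, dark air).
#' @param gre_echo_decay multiplicative intensity decay between successive
#'   echoes.
#' @param snr b = 0 signal-to-noise ratio for the simulated microscopy
#'   images (gradient echo, DTI).
#' @param snr_dmri b = 0 signal-to-noise ratio for the 160 um dMRI series;
#'   higher than the microscopy SNR because the voxel volume is ~500x
#'   larger. The default keeps the Rician magnitude floor below the
#'   highest-b fluid signal, matching the observation that high-b
#'   measurements in fluid-dominated voxels show minimal Rician bias.
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param sample_effect_sd SD of the per-sample, per-component
#'   heterogeneity perturbation: each sample draws a flat multiplicative
#'   signal scale and a common multiplier on the compartment diffusivities
#'   (both Gaussian around 1 with this SD), emulating genuine inter-sample
#'   variation in component diffusion properties (0 disables).
#' @param tube_radius_um,tissue_radius_um tube and tissue-core radii (um);
#'   defaults scale with the grid so small test grids remain valid.
#' @param seed integer seed; all simulators are deterministic given the
#'   config.
#' @param sample_id label attached to simulated data (provenance for
#'   per-sample analyses).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(240, 240, 320),
                           voxel_um = 20,
                           gland_density = 0.42,
                           lumen_radius_range = c(40, 120),
                           epithelium_shell_range = c(25, 45),
                           stroma_lambda = c(1.4, 0.6),
                           epithelium_d = 0.8,
                           lumen_d = 2.0,
                           component_params = list(
                             epithelium = reference_params("ballsphere",
                                                           "epithelium"),
                             stroma = reference_params("ballsphere",
                                                       "stroma"),
                             lumen_d = 2.0),
                           gre_intensities = c(epithelium = 0.55,
                                               stroma = 0.45, lumen = 1.0,
                                               medium = 1.0, air = 0),
                           gre_echo_decay = 0.88,
                           snr = 30,
                           snr_dmri = 80,
                           noise_model = c("rician", "gaussian", "none"),
                           sample_effect_sd = 0.13,
                           tube_radius_um = NULL,
                           tissue_radius_um = NULL,
                           seed = 1L,
                           sample_id = "sample1") {
  noise_model <- match.arg(noise_model)
  fov_xy <- min(grid_shape[1:2]) * voxel_um
  if (is.null(tube_radius_um)) tube_radius_um <- 0.42 * fov_xy
  if (is.null(tissue_radius_um)) tissue_radius_um <- 0.30 * fov_xy
  stopifnot(snr > 0, gland_density >= 0, gland_density < 1,
            tissue_radius_um < tube_radius_um)
  structure(list(grid_shape = as.integer(grid_shape), voxel_um = voxel_um,
                 gland_density = gland_density,
                 lumen_radius_range = lumen_radius_range,
                 epithelium_shell_range = epithelium_shell_range,
                 stroma_lambda = stroma_lambda,
                 epithelium_d = epithelium_d, lumen_d = lumen_d,
                 component_params = component_params,
                 gre_intensities = gre_intensities,
                 gre_echo_decay = gre_echo_decay,
                 snr = snr, snr_dmri = snr_dmri, noise_model = noise_model,
                 sample_effect_sd = sample_effect_sd,
                 tube_radius_um = tube_radius_um,
                 tissue_radius_um = tissue_radius_um,
                 seed = as.integer(seed), sample_id = sample_id),
            class = "phantom_config")
}

# Voxel-centre coordinate grids (um), origin at the volume centre in x/y.
.centre_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

# Magnitude noise applied to a signal array.
.apply_noise <- function(s, sigma, noise_model) {
  if (noise_model == "none" || sigma <= 0) return(s)
  n <- length(s)
  if (noise_model == "gaussian") return(s + stats::rnorm(n, 0, sigma))
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Generate a labeled synthetic tissue phantom
#'
#' A cylindrical tissue core inside a medium-filled tube (air outside the
#' tube): non-overlapping spherical lumens, each wrapped by an epithelial
#' shell, are packed into stroma until the target gland density is reached.
#' Stroma voxels carry a smooth random fiber orientation field.
#'
#' @param config a [phantom_config()].
#' @return A list of class `esl_phantom`: `labels` (3D integer array, coding
#'   per [esl_labels()]), `voxel_um`, `fiber_dirs` (x/y/z component arrays),
#'   `config`, and realized per-component `fractions` over the tube
#'   interior.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  L <- esl_labels()
  dims <- config$grid_shape
  h <- config$voxel_um
  x <- .centre_coords(dims[1], h)
  y <- .centre_coords(dims[2], h)
  z <- .centre_coords(dims[3], h)
  r2 <- outer(x^2, y^2, "+")
  labels <- array(L["air"], dims)
  in_tube <- r2 <= config$tube_radius_um^2
  in_tissue <- r2 <= config$tissue_radius_um^2
  labels[rep(in_tube, dims[3])] <- L["medium"]
  labels[rep(in_tissue, dims[3])] <- L["stroma"]

  n_tissue <- sum(in_tissue) * dims[3]
  target <- config$gland_density * n_tissue
  gland_vox <- 0
  centres <- matrix(numeric(0), 0, 3)
  lumen_r <- numeric(0)
  shell_w <- numeric(0)
  attempts <- 0
  mean_gland_vol <- 4 / 3 * pi * mean(config$lumen_radius_range +
                                        config$epithelium_shell_range)^3 /
    h^3
  max_attempts <- 2000 + 200 * ceiling(target / max(mean_gland_vol, 1))
  zmin <- z[1] + max(config$lumen_radius_range) +
    max(config$epithelium_shell_range)
  zmax <- z[dims[3]] - (zmin - z[1])
  while (gland_vox < target && attempts < max_attempts) {
    attempts <- attempts + 1
    rl <- stats::runif(1, config$lumen_radius_range[1],
                       config$lumen_radius_range[2])
    sh <- stats::runif(1, config$epithelium_shell_range[1],
                       config$epithelium_shell_range[2])
    ro <- rl + sh
    rmax <- config$tissue_radius_um - ro
    if (rmax <= 0 || zmax <= zmin) break
    rad <- sqrt(stats::runif(1)) * rmax
    th <- stats::runif(1, 0, 2 * pi)
    c0 <- c(rad * cos(th), rad * sin(th), stats::runif(1, zmin, zmax))
    # epithelial shells may touch; lumens must stay separated by a shell
    if (nrow(centres) > 0) {
      d <- sqrt(colSums((t(centres) - c0)^2))
      if (any(d < lumen_r + rl + pmax(shell_w, sh))) next
    }
    ix <- which(abs(x - c0[1]) <= ro)
    iy <- which(abs(y - c0[2]) <= ro)
    iz <- which(abs(z - c0[3]) <= ro)
    dx2 <- (x[ix] - c0[1])^2
    dy2 <- (y[iy] - c0[2])^2
    dz2 <- (z[iz] - c0[3])^2
    dd <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- labels[ix, iy, iz]
    shell <- dd <= ro^2 & sub == L["stroma"]
    core <- dd <= rl^2 & sub == L["stroma"]
    sub[shell] <- L["epithelium"]
    sub[core] <- L["lumen"]
    labels[ix, iy, iz] <- sub
    gland_vox <- gland_vox + sum(shell)
    centres <- rbind(centres, c0)
    lumen_r <- c(lumen_r, rl)
    shell_w <- c(shell_w, sh)
  }
  if (config$gland_density > 0 && gland_vox < 0.8 * target)
    stop("gland packing failed: reached density ",
         signif(gland_vox / n_tissue, 3), " of requested ",
         config$gland_density)

  # Smooth random fiber orientation field: three low-frequency cosine
  # mixtures, normalised per voxel.
  fov <- dims * h
  field <- vector("list", 3)
  for (cmp in 1:3) {
    acc <- array(0, dims)
    for (w in 1:4) {
      k <- stats::runif(3, 0.5, 2.5) * 2 * pi / fov
      ph <- stats::runif(1, 0, 2 * pi)
      a <- stats::rnorm(1)
      acc <- acc + a * cos(outer(outer(k[1] * x, k[2] * y, "+"),
                                 k[3] * z, "+") + ph)
    }
    field[[cmp]] <- acc
  }
  nrm <- sqrt(field[[1]]^2 + field[[2]]^2 + field[[3]]^2)
  tiny <- nrm < 1e-8
  field[[3]][tiny] <- 1
  nrm[tiny] <- 1
  fiber <- lapply(field, function(f) f / nrm)

  tube_n <- sum(in_tube) * dims[3]
  lab_tube <- labels[rep(in_tube, dims[3])]
  fr <- vapply(L[1:4], function(v) sum(lab_tube == v) / tube_n, numeric(1))
  structure(list(labels = labels, voxel_um = h,
                 fiber_dirs = fiber, config = config,
                 fractions = fr),
            class = "esl_phantom")
}

#' Simulate multi-gradient-echo microscopy images of a phantom
#'
#' Four echo volumes at microscopy resolution; per-component intensity
#' decays mildly across echoes, fluid (lumen/medium) stays brighter than
#' tissue, air is dark. Noise per the config's noise model, with
#' sigma = max intensity / snr.
#'
#' @param phantom an `esl_phantom`.
#' @param config the [phantom_config()]; defaults to the phantom's own.
#' @return List of class `esl_gre`: `echoes` (list of 4 arrays),
#'   `voxel_um`.
#' @export
simulate_gre <- function(phantom, config = phantom$config) {
  set.seed(config$seed + 1L)
  inten <- config$gre_intensities[c("epithelium", "stroma", "lumen",
                                    "medium", "air")]
  base <- array(inten[phantom$labels], dim(phantom$labels))
  sigma <- if (config$noise_model == "none") 0 else
    max(inten) / config$snr
  echoes <- lapply(1:4, function(e) {
    s <- base * config$gre_echo_decay^(e - 1)
    array(.apply_noise(s, sigma, config$noise_model), dim(base))
  })
  structure(list(echoes = echoes, voxel_um = phantom$voxel_um),
            class = "esl_gre")
}

# Block-average a hi-res array by integer factors (means over blocks).
.block_mean <- function(vol, factors) {
  d <- dim(vol)
  stopifnot(all(d %% factors == 0))
  d2 <- d %/% factors
  a <- array(vol, c(factors[1], d2[1], factors[2], d2[2], factors[3], d2[3]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(factors), prod(d2))
  out <- colMeans(a)
  dim(out) <- d2
  out
}

#' Simulate the DTI acquisition of a phantom
#'
#' Noiseless directional signals are evaluated at microscopy resolution
#' (stroma: axially symmetric tensor aligned with the fiber field;
#' epithelium: isotropic; lumen/medium: free diffusion at the medium
#' diffusivity; air: zero) and block-averaged to the 40 um DTI grid before
#' noise is applied.
#'
#' @param phantom an `esl_phantom`.
#' @param config the [phantom_config()].
#' @param out_voxel_um DTI voxel size (must be an integer multiple of the
#'   microscopy voxel).
#' @return List of class `esl_dti`: `b0` (list of 2 volumes), `dwi` (list
#'   of 6), `b`, `delta`, `Delta`, `directions`, `voxel_um`.
#' @export
simulate_dti <- function(phantom, config = phantom$config,
                         out_voxel_um = 40) {
  set.seed(config$seed + 2L)
  prot <- dti_protocol()
  f <- out_voxel_um / phantom$voxel_um
  stopifnot(abs(f - round(f)) < 1e-9)
  f <- rep(as.integer(round(f)), 3)
  L <- esl_labels()
  lab <- phantom$labels
  lam <- config$stroma_lambda
  b <- prot$b
  iso_d <- c(config$epithelium_d, NA, config$lumen_d, config$lumen_d, 0)
  is_stroma <- lab == L["stroma"]
  is_air <- lab == L["air"]
  base_iso <- array(0, dim(lab))
  for (cmp in c(1L, 3L, 4L)) {
    m <- lab == cmp
    base_iso[m] <- exp(-b * iso_d[cmp])
  }
  sigma <- if (config$noise_model == "none") 0 else 1 / config$snr
  b0_hi <- array(as.numeric(!is_air), dim(lab))
  b0 <- lapply(1:2, function(i) {
    v <- .block_mean(b0_hi, f)
    array(.apply_noise(v, sigma, config$noise_model), dim(v))
  })
  dirs <- prot$directions
  dwi <- lapply(seq_len(nrow(dirs)), function(i) {
    g <- dirs[i, ]
    dot <- g[1] * phantom$fiber_dirs[[1]] + g[2] * phantom$fiber_dirs[[2]] +
      g[3] * phantom$fiber_dirs[[3]]
    s <- base_iso
    s[is_stroma] <- exp(-b * (lam[2] + (lam[1] - lam[2]) * dot[is_stroma]^2))
    v <- .block_mean(s, f)
    array(.apply_noise(v, sigma, config$noise_model), dim(v))
  })
  structure(list(b0 = b0, dwi = dwi, b = b, delta = prot$delta,
                 Delta = prot$Delta, directions = dirs,
                 voxel_um = out_voxel_um),
            class = "esl_dti")
}

# Draw one sample's heterogeneity perturbation: per tissue component, a
# flat signal scale and a common multiplier on the compartment
# diffusivities (emulating e.g. sample-to-sample differences in fixation).
.sample_perturbation <- function(sd_h) {
  if (sd_h <= 0)
    return(list(E = c(scale = 1, dmult = 1), S = c(scale = 1, dmult = 1)))
  draw <- function() c(scale = 1 + stats::rnorm(1, 0, sd_h),
                       dmult = 1 + stats::rnorm(1, 0, sd_h))
  list(E = draw(), S = draw())
}

# Noiseless normalised component signals over the STEAM sequences,
# including the per-sample heterogeneity perturbation.
.component_signals <- function(config, sequences,
                               perturb = .sample_perturbation(0)) {
  one <- function(params, pert) {
    p <- params
    p[c("D_sphere", "D_ball")] <- pmax(p[c("D_sphere", "D_ball")] *
                                         pert[["dmult"]], 1e-6)
    model_forward("ballsphere", p, sequences) * pert[["scale"]]
  }
  list(E = one(config$component_params$epithelium, perturb$E),
       S = one(config$component_params$stroma, perturb$S),
       L = exp(-sequences$b * config$component_params$lumen_d))
}

#' Simulate the multidimensional dMRI acquisition of a phantom
#'
#' Each low-resolution voxel's noiseless signal is the exact volume-
#' fraction-weighted sum of its component signals (epithelium and stroma via
#' the ball+sphere forward model, lumen/medium via free diffusion, air
#' contributing zero), evaluated per STEAM sequence. Per-direction noise is
#' applied before any averaging; the spin-echo b = 0 volume is simulated the
#' same way. When `config$sample_effect_sd > 0` a per-sample multiplicative
#' perturbation (one draw per component) emulates inter-sample heterogeneity
#' in component diffusion properties.
#'
#' @param phantom an `esl_phantom`.
#' @param protocol an `esl_protocol` (default [canonical_protocol()]).
#' @param config the [phantom_config()].
#' @param out_voxel_um dMRI voxel edge (integer multiple of the microscopy
#'   voxel; default 160).
#' @return List of class `esl_dmri`: `dwi` (list over sequences, each a
#'   list of `n_directions` volumes), `b0` (one volume), `protocol`,
#'   `fractions` (true per-voxel component fractions: arrays `f_E`, `f_S`,
#'   `f_L` (lumen + medium), `f_U` (air)), `perturb`, `sample_id`,
#'   `voxel_um`.
#' @export
simulate_dmri <- function(phantom, protocol = canonical_protocol(),
                          config = phantom$config, out_voxel_um = 160) {
  set.seed(config$seed + 3L)
  f <- out_voxel_um / phantom$voxel_um
  stopifnot(abs(f - round(f)) < 1e-9)
  f <- rep(as.integer(round(f)), 3)
  L <- esl_labels()
  lab <- phantom$labels
  frac <- list(
    f_E = .block_mean(array(as.numeric(lab == L["epithelium"]), dim(lab)), f),
    f_S = .block_mean(array(as.numeric(lab == L["stroma"]), dim(lab)), f),
    f_L = .block_mean(array(as.numeric(lab == L["lumen"] |
                                         lab == L["medium"]), dim(lab)), f),
    f_U = .block_mean(array(as.numeric(lab == L["air"]), dim(lab)), f)
  )
  perturb <- .sample_perturbation(config$sample_effect_sd)
  seqs <- steam_sequences(protocol)
  comp <- .component_signals(config, seqs, perturb)
  sigma <- if (config$noise_model == "none") 0 else 1 / config$snr_dmri
  nd <- seqs$n_directions[1]
  dwi <- lapply(seq_len(nrow(seqs)), function(i) {
    s <- frac$f_E * comp$E[i] + frac$f_S * comp$S[i] + frac$f_L * comp$L[i]
    lapply(seq_len(nd), function(d)
      array(.apply_noise(s, sigma, config$noise_model), dim(s)))
  })
  names(dwi) <- seqs$id
  s_b0 <- frac$f_E + frac$f_S + frac$f_L
  b0 <- array(.apply_noise(s_b0, sigma, config$noise_model), dim(s_b0))
  structure(list(dwi = dwi, b0 = b0, protocol = protocol,
                 fractions = frac, perturb = perturb,
                 sample_id = config$sample_id,
                 voxel_um = out_voxel_um),
            class = "esl_dmri")
}

#' Simulate a multi-sample cohort of analysis-ready dMRI voxels
#'
#' Fast generator for calibration and null experiments at the level the
#' voxelwise analysis operates on: per-voxel ESL volume fractions drawn
#' from a Dirichlet distribution, normalised direction-averaged signals
#' built from the exact linear component mixture, per-sample component
#' perturbations, per-direction magnitude noise, and noisy b = 0
#' normalisation -- the same signal chain as the image-based pipeline
#' without the imaging stages.
#'
#' @param n_samples number of tissue samples.
#' @param voxels_per_sample voxels per sample.
#' @param protocol an `esl_protocol`.
#' @param config a [phantom_config()] supplying component parameters,
#'   noise model, snr and `sample_effect_sd`.
#' @param fraction_alpha Dirichlet concentration for (f_E, f_S, f_L); the
#'   default mimics benign tissue composition (mean ~ 28/58/14%).
#' @param downsample_gain SNR gain of the block-downsampling step the
#'   cohort voxels have implicitly undergone (default sqrt(18), the
#'   3 x 3 x 2 block); per-direction noise uses sigma = 1/(snr * gain).
#' @param component_overrides optional named list replacing entries of
#'   `config$component_params` (e.g. a lesion with raised epithelial sphere
#'   fraction).
#' @param seed integer seed.
#' @return List of class `esl_cohort`: `signal` (voxels x sequences matrix
#'   of normalised measurements), `fractions` (data frame `f_E`, `f_S`,
#'   `f_L`), `sample_id`, `sequences`, `perturb` (per-sample draws).
#' @export
simulate_voxel_cohort <- function(n_samples, voxels_per_sample,
                                  protocol = canonical_protocol(),
                                  config = phantom_config(),
                                  fraction_alpha = c(2.2, 4.6, 1.2),
                                  component_overrides = NULL,
                                  downsample_gain = sqrt(18),
                                  seed = 1L) {
  set.seed(seed)
  if (!is.null(component_overrides))
    config$component_params[names(component_overrides)] <-
      component_overrides
  seqs <- steam_sequences(protocol)
  n_seq <- nrow(seqs)
  nd <- seqs$n_directions[1]
  sigma <- if (config$noise_model == "none") 0 else
    1 / (config$snr_dmri * downsample_gain)
  all_sig <- NULL
  all_fr <- NULL
  sample_id <- character(0)
  perturb <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    nv <- voxels_per_sample
    g <- matrix(stats::rgamma(nv * 3, shape = rep(fraction_alpha,
                                                  each = nv)), nv, 3)
    fr <- g / rowSums(g)
    colnames(fr) <- c("f_E", "f_S", "f_L")
    eps <- .sample_perturbation(config$sample_effect_sd)
    comp <- .component_signals(config, seqs, eps)
    clean <- fr[, "f_E"] %o% comp$E + fr[, "f_S"] %o% comp$S +
      fr[, "f_L"] %o% comp$L
    meas <- matrix(0, nv, n_seq)
    for (d in seq_len(nd))
      meas <- meas + .apply_noise(clean, sigma, config$noise_model)
    meas <- meas / nd
    b0 <- .apply_noise(rep(1, nv), sigma, config$noise_model)
    meas <- meas / b0
    all_sig <- rbind(all_sig, meas)
    all_fr <- rbind(all_fr, fr)
    sample_id <- c(sample_id, rep(sprintf("s%02d", s), nv))
    perturb[[s]] <- eps
  }
  colnames(all_sig) <- seqs$id
  structure(list(signal = all_sig, fractions = as.data.frame(all_fr),
                 sample_id = sample_id, sequences = seqs,
                 perturb = perturb),
            class = "esl_cohort")
}
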