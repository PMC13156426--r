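test_that("phantom generation is deterministic and respects its config", {
  cfg <- test_phantom_config()
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$labels, ph2$labels)
  expect_identical(ph1$fiber_dirs, ph2$fiber_dirs)
  L <- esl_labels()
  expect_true(all(ph1$labels %in% L))
  # realized gland (lumen + epithelium) fraction near the requested density
  tissue <- ph1$labels %in% L[c("epithelium", "stroma", "lumen")]
  gland <- ph1$labels %in% L[c("epithelium", "lumen")]
  expect_lt(abs(sum(gland) / sum(tissue) - cfg$gland_density), 0.05)
  # fiber directions are unit vectors on stroma voxels
  n2 <- ph1$fiber_dirs[[1]]^2 + ph1$fiber_dirs[[2]]^2 + ph1$fiber_dirs[[3]]^2
  expect_equal(range(n2[ph1$labels == L["stroma"]]), c(1, 1),
               tolerance = 1e-9)
})

test_that("zero gland density yields pure stroma tissue", {
  cfg <- test_phantom_config(gland_density = 0)
  ph <- generate_phantom(cfg)
  L <- esl_labels()
  expect_false(any(ph$labels %in% L[c("epithelium", "lumen")]))
  expect_gt(sum(ph$labels == L["stroma"]), 0)
})

test_that("gradient-echo simulation has the configured contrast", {
  ph <- test_phantom()
  cfg <- ph$config
  gre <- simulate_gre(ph, cfg)
  L <- esl_labels()
  # noiseless: first echo equals the configured component intensity
  expect_equal(unique(gre$echoes[[1]][ph$labels == L["stroma"]]),
               unname(cfg$gre_intensities["stroma"]))
  expect_equal(unique(gre$echoes[[1]][ph$labels == L["air"]]), 0)
  for (e in 1:4) {
    expect_gt(mean(gre$echoes[[e]][ph$labels == L["lumen"]]),
              mean(gre$echoes[[e]][ph$labels == L["stroma"]]))
  }
  # echoes decay multiplicatively
  expect_equal(mean(gre$echoes[[2]][ph$labels == L["stroma"]]) /
                 mean(gre$echoes[[1]][ph$labels == L["stroma"]]),
               cfg$gre_echo_decay, tolerance = 1e-12)
})

test_that("Rician background magnitude matches the small-signal limit", {
  cfg <- test_phantom_config(noise_model = "rician", snr = 30)
  ph <- generate_phantom(cfg)
  gre <- simulate_gre(ph, cfg)
  sigma <- max(cfg$gre_intensities) / cfg$snr
  bg <- gre$echoes[[1]][ph$labels == esl_labels()["air"]]
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 5e-2)
})

test_that("DTI simulation honours component diffusion models", {
  ph <- test_phantom()
  dti <- simulate_dti(ph)
  L <- esl_labels()
  f <- 2L  # 20 -> 40 um
  lab_low <- ph$labels[seq(1, dim(ph$labels)[1], by = f), , ]
  # pure lumen/medium blocks attenuate as free diffusion at 2.0 um^2/ms
  med_frac <- esldmri:::.block_mean(
    array(as.numeric(ph$labels == L["medium"]), dim(ph$labels)), rep(f, 3))
  pure_med <- med_frac == 1
  skip_if(sum(pure_med) == 0)
  for (i in 1:6) {
    vals <- dti$dwi[[i]][pure_med] / dti$b0[[1]][pure_med]
    expect_equal(unique(round(vals, 9)), round(exp(-1.2 * 2.0), 9))
  }
  # isotropic components: identical signal in all six directions
  arr <- sapply(dti$dwi, function(v) v[pure_med][1])
  expect_equal(max(arr) - min(arr), 0)
})

test_that("tensor refit of pure-stroma DTI recovers the generating FA and MD", {
  cfg <- test_phantom_config(gland_density = 0)
  ph <- generate_phantom(cfg)
  dti <- simulate_dti(ph)
  tm <- fit_dti(dti)
  L <- esl_labels()
  f <- 2L
  str_frac <- esldmri:::.block_mean(
    array(as.numeric(ph$labels == L["stroma"]), dim(ph$labels)), rep(f, 3))
  pure <- str_frac == 1
  # closed-form values for the axially symmetric (1.4, 0.6, 0.6) tensor
  lam <- c(1.4, 0.6, 0.6)
  md_true <- mean(lam)
  fa_true <- sqrt(1.5 * sum((lam - md_true)^2) / sum(lam^2))
  expect_equal(fa_true, 0.4886778, tolerance = 1e-6)
  # 40 um blocks average signals over slightly varying fiber directions, so
  # the refit tensor is mildly more isotropic than the generating one
  expect_equal(median(tm$md[pure]), md_true, tolerance = 1e-2)
  expect_equal(median(tm$fa[pure]), fa_true, tolerance = 5e-2)
  # comfortably above the stroma segmentation threshold
  expect_gt(median(tm$md[pure] * tm$fa[pure]), diffusivity_to_internal(1.4e-4))
})

test_that("dMRI simulation mixes component signals exactly", {
  ph <- test_phantom()
  cfg <- ph$config
  dmri <- simulate_dmri(ph)
  seqs <- steam_sequences()
  comp <- esldmri:::.component_signals(cfg, seqs)
  fr <- dmri$fractions
  for (i in c(1, 5, 10)) {
    mix <- fr$f_E * comp$E[i] + fr$f_S * comp$S[i] + fr$f_L * comp$L[i]
    expect_equal(max(abs(dmri$dwi[[i]][[1]] - mix)), 0)
  }
  # an all-medium phantom gives the free-diffusion value at every voxel
  med_ph <- ph
  med_ph$labels[] <- esl_labels()["medium"]
  med_dmri <- simulate_dmri(med_ph)
  expect_equal(unique(as.vector(med_dmri$dwi[[1]][[1]])), exp(-2.0),
               tolerance = 1e-12)
  # fractions per voxel sum to one
  expect_equal(max(abs(fr$f_E + fr$f_S + fr$f_L + fr$f_U - 1)), 0,
               tolerance = 1e-12)
})

test_that("voxel cohorts are reproducible with valid compositions", {
  cfg <- phantom_config(sample_effect_sd = 0.1)
  c1 <- simulate_voxel_cohort(3, 10, config = cfg, seed = 9)
  c2 <- simulate_voxel_cohort(3, 10, config = cfg, seed = 9)
  expect_identical(c1$signal, c2$signal)
  expect_equal(rowSums(as.matrix(c1$fractions)), rep(1, 30),
               tolerance = 1e-12)
  expect_equal(length(unique(c1$sample_id)), 3)
  expect_equal(dim(c1$signal), c(30, 10))
})
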