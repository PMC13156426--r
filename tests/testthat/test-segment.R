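test_that("echo averaging is the voxelwise mean with SNR gain", {
  v <- array(2, c(3, 3, 3))
  expect_equal(average_echoes(list(v, v, v, v)), v)
  echoes <- lapply(4:1, function(k) array(k, c(2, 2, 2)))
  expect_equal(average_echoes(echoes)[1, 1, 1], 2.5)
  set.seed(6)
  noisy <- lapply(1:4, function(i) array(rnorm(8000), c(20, 20, 20)))
  expect_equal(sd(average_echoes(noisy)), 0.5, tolerance = 0.05)
  expect_error(average_echoes(list(v)), "at least 2")
})

test_that("lumen/air thresholds separate phantom components exactly when noiseless", {
  ph <- test_phantom()
  gre <- simulate_gre(ph)
  g <- average_echoes(gre)
  L <- esl_labels()
  medium_vals <- g[ph$labels == L["medium"]]
  # zero-spread medium statistics warn but proceed
  expect_warning(la <- segment_lumen_air(g, medium_vals), "degenerate")
  expect_identical(la$lumen, (ph$labels == L["lumen"]) |
                     (ph$labels == L["medium"]))
  expect_identical(la$air, ph$labels == L["air"])
  # everything below the air threshold leaves no tissue
  la2 <- suppressWarnings(
    segment_lumen_air(g * 0, medium_vals,
                      segmentation_config(air_min_threshold = 0.1)))
  expect_true(all(la2$air))
  expect_false(any(la2$lumen))
})

test_that("tensor fit is exact for noiseless single-tensor signals", {
  dirs <- encoding_directions()
  b <- 1.2
  make_dti <- function(Dmat) {
    sig <- apply(dirs, 1, function(g) exp(-b * drop(t(g) %*% Dmat %*% g)))
    list(b0 = list(array(1, c(2, 2, 2))),
         dwi = lapply(sig, function(s) array(s, c(2, 2, 2))),
         b = b, directions = dirs, voxel_um = 40)
  }
  # isotropic: MD = D, FA = 0
  tm <- fit_dti(make_dti(diag(2, 3)))
  expect_equal(tm$md[1, 1, 1], 2.0, tolerance = 1e-9)
  expect_equal(tm$fa[1, 1, 1], 0, tolerance = 1e-9)
  # axially symmetric (1.4, 0.6, 0.6): closed-form MD and FA
  tm <- fit_dti(make_dti(diag(c(1.4, 0.6, 0.6))))
  expect_equal(tm$md[1, 1, 1], 13 / 15, tolerance = 1e-9)
  expect_equal(tm$fa[1, 1, 1], 0.4886778, tolerance = 1e-6)
  # oracle equivalence: all six elements of a random SPD tensor
  set.seed(8)
  A <- matrix(rnorm(9, 0, 0.4), 3)
  Dmat <- crossprod(A) + diag(0.3, 3)
  tm <- fit_dti(make_dti(Dmat))
  est <- tm$tensor[1, ]
  truth <- c(Dmat[1, 1], Dmat[2, 2], Dmat[3, 3], Dmat[1, 2], Dmat[1, 3],
             Dmat[2, 3])
  expect_equal(est, truth, tolerance = 1e-9, ignore_attr = TRUE)
  # identical signals in every direction: FA = 0
  flat <- make_dti(diag(1, 3))
  tm <- fit_dti(flat)
  expect_equal(tm$fa[2, 2, 2], 0, tolerance = 1e-9)
  # non-positive signal invalidates the voxel
  bad <- make_dti(diag(1, 3))
  bad$dwi[[1]][1, 1, 1] <- -1
  tm <- fit_dti(bad)
  expect_false(tm$valid[1, 1, 1])
  expect_true(tm$valid[2, 2, 2])
})

test_that("trilinear upsampling preserves constants and linear ramps", {
  v <- array(3, c(4, 4, 4))
  u <- upsample_linear(v, 40, 20)
  expect_equal(dim(u), c(8, 8, 8))
  expect_equal(unique(as.vector(u)), 3)
  # ramp along x at source centres (i - 0.5) * 40: value = x position
  ramp <- array(rep((1:8 - 0.5) * 40, times = 16), c(8, 4, 4))
  u <- upsample_linear(ramp, 40, 20)
  # interior target centres take exact ramp values
  expect_equal(u[3:14, 2, 2], (3:14 - 0.5) * 20, tolerance = 1e-12)
  expect_error(upsample_linear(v, 40, 80), "finer")
})

test_that("stroma criterion thresholds diffusivity-weighted anisotropy", {
  md <- array(c(0.867, 0.2), c(2, 1, 1))
  fa <- array(c(0.458, 0.1), c(2, 1, 1))
  tm <- structure(list(md = md, fa = fa,
                       valid = array(TRUE, c(2, 1, 1))),
                  class = "tensor_maps")
  st <- segment_stroma(tm)
  expect_true(st[1, 1, 1])    # 0.397 um^2/ms > 0.14
  expect_false(st[2, 1, 1])   # 0.02 < 0.14
  # FA = 0 everywhere: empty stroma mask
  tm$fa[] <- 0
  expect_false(any(segment_stroma(tm)))
})

test_that("label composition applies the stated precedence", {
  d <- c(2, 2, 1)
  lum <- array(c(TRUE, FALSE, FALSE, TRUE), d)
  str <- array(c(TRUE, TRUE, FALSE, FALSE), d)
  air <- array(FALSE, d)
  lab <- compose_esl(lum, str, air)
  L <- esl_labels()
  expect_equal(as.vector(lab),
               as.vector(L[c("lumen", "stroma", "epithelium", "lumen")]),
               ignore_attr = TRUE)
  # empty lumen and stroma: all tissue epithelium
  lab <- compose_esl(array(FALSE, d), array(FALSE, d), air)
  expect_true(all(lab == L["epithelium"]))
  # ROI restriction marks outside voxels unclassified
  roi <- array(c(TRUE, TRUE, FALSE, FALSE), d)
  lab <- compose_esl(lum, str, air, roi)
  expect_equal(as.vector(lab[, 2, 1]), rep(unname(L["air"]), 2))
})

test_that("volume fractions count label voxels and sum to one", {
  L <- esl_labels()
  lab <- array(L["epithelium"], c(24, 24, 16))
  fm <- volume_fractions(lab, 20, c(480, 480, 320))
  expect_equal(dim(fm$f_E), c(1, 1, 1))   # 24 x 24 x 16 = 9216 voxels
  expect_equal(fm$f_E[1, 1, 1], 1)
  # half lumen / half stroma
  lab[1:12, , ] <- L["lumen"]
  lab[13:24, , ] <- L["stroma"]
  fm <- volume_fractions(lab, 20, c(480, 480, 320))
  expect_equal(fm$f_L[1, 1, 1], 0.5)
  expect_equal(fm$f_S[1, 1, 1], 0.5)
  expect_error(volume_fractions(lab, 20, c(470, 480, 320)),
               "integer multiples")
  # sums to one everywhere on a phantom segmentation
  ph <- test_phantom()
  fm <- volume_fractions(ph$labels, 20, c(160, 160, 160))
  total <- fm$f_E + fm$f_S + fm$f_L + fm$f_U
  expect_lt(max(abs(total - 1)), 1e-9)
})

test_that("segmentation masks respond monotonically to their thresholds", {
  ph <- test_phantom()
  g <- average_echoes(simulate_gre(ph))
  L <- esl_labels()
  med <- g[ph$labels == L["medium"]]
  sizes <- vapply(c(0.9, 0.7, 0.5), function(tv)
    sum(suppressWarnings(segment_lumen_air(
      g, med, segmentation_config(lumen_threshold_value = tv)))$lumen),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))   # lowering the threshold grows lumen
  dti <- simulate_dti(ph)
  tm <- fit_dti(dti)
  s_sizes <- vapply(c(1.0e-4, 1.4e-4, 2.0e-4), function(thr)
    sum(segment_stroma(tm, segmentation_config(dfa_threshold_mm2_s = thr))),
    numeric(1))
  expect_true(all(diff(s_sizes) <= 0))  # raising the cutoff shrinks stroma
})

test_that("threshold sensitivity sweep reproduces the baseline at its centre", {
  ph <- test_phantom()
  g <- average_echoes(simulate_gre(ph))
  dti <- simulate_dti(ph)
  up <- function(v) upsample_linear(v, 40, 20)
  tm <- fit_dti(list(b0 = lapply(dti$b0, up), dwi = lapply(dti$dwi, up),
                     b = dti$b, directions = dti$directions))
  L <- esl_labels()
  med <- g[ph$labels == L["medium"]]
  cfg <- segmentation_config()
  tab1 <- suppressWarnings(
    threshold_sensitivity(g, tm, med, cfg,
                          lumen_values = cfg$lumen_threshold_value,
                          dfa_values_mm2_s = cfg$dfa_threshold_mm2_s))
  expect_equal(nrow(tab1), 1)
  la <- suppressWarnings(segment_lumen_air(g, med, cfg))
  st <- segment_stroma(tm, cfg, exclude = la$lumen | la$air)
  lab <- compose_esl(la$lumen, st, la$air)
  expect_equal(tab1$f_S, mean(lab == L["stroma"]))
  tab <- suppressWarnings(threshold_sensitivity(g, tm, med, cfg))
  expect_equal(nrow(tab), 9)
  # stroma fraction decreases as the D*FA cutoff rises
  at_base_lumen <- tab[tab$lumen_threshold_value == cfg$lumen_threshold_value, ]
  ord <- order(at_base_lumen$dfa_threshold_mm2_s)
  expect_true(all(diff(at_base_lumen$f_S[ord]) <= 0))
})
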