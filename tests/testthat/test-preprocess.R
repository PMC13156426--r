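test_that("MP-PCA estimates the noise level of a pure-noise stack", {
  set.seed(21)
  sigma <- 0.05
  stack <- array(rnorm(12 * 12 * 12 * 16, 0, sigma), c(12, 12, 12, 16))
  out <- mppca_denoise(stack)
  expect_equal(median(out$sigma), sigma, tolerance = 0.1)
  # residual mean compatible with zero (unbiasedness)
  resid <- stack - out$denoised
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 2 * se + 1e-6)
})

test_that("MP-PCA preserves a noiseless low-rank stack", {
  base <- array(runif(10 * 10 * 10), c(10, 10, 10))
  weights <- seq(0.5, 1.5, length.out = 8)
  stack <- array(0, c(10, 10, 10, 8))
  for (i in 1:8) stack[, , , i] <- base * weights[i]
  out <- mppca_denoise(stack)
  rmse <- sqrt(mean((out$denoised - stack)^2))
  expect_lt(rmse / mean(abs(stack)), 1e-8)
})

test_that("MP-PCA rejects invalid configurations", {
  stack <- array(0, c(4, 4, 4, 3))
  expect_error(mppca_denoise(stack, patch_edge = 4), "odd")
  expect_error(mppca_denoise(stack, patch_edge = 5), "patch larger")
  expect_error(mppca_denoise(array(0, c(6, 6, 6, 1))), "at least 2")
})

test_that("direction averaging is the voxelwise mean", {
  v <- array(1:8, c(2, 2, 2))
  expect_equal(direction_average(list(v, v, v)), v)
  vols <- lapply(1:6, function(i) array(i, c(2, 2, 2)))
  expect_equal(direction_average(vols)[1, 1, 1], 3.5)
  expect_error(direction_average(vols, n_directions = 5), "expected 5")
  # SD reduction by sqrt(6)
  set.seed(3)
  noisy <- lapply(1:6, function(i) array(rnorm(20^3), c(20, 20, 20)))
  expect_equal(sd(direction_average(noisy)), 1 / sqrt(6), tolerance = 0.05)
})

test_that("block downsampling averages blocks and tracks voxel size", {
  set.seed(4)
  v <- array(rnorm(30 * 30 * 80), c(30, 30, 80))
  attr(v, "voxel_um") <- c(160, 160, 160)
  out <- block_downsample(v, c(3, 3, 2))
  expect_equal(dim(out), c(10, 10, 40))
  expect_equal(attr(out, "voxel_um"), c(480, 480, 320))
  expect_equal(out[1, 1, 1], mean(v[1:3, 1:3, 1:2]))
  # constant volume is unchanged; noise SD drops by sqrt(18)
  expect_equal(unique(as.vector(block_downsample(array(2, c(6, 6, 4)),
                                                 c(3, 3, 2)))), 2)
  expect_equal(sd(v) / sd(out), sqrt(18), tolerance = 0.05)
  expect_error(block_downsample(array(0, c(7, 6, 4)), c(3, 3, 2)),
               "not divisible")
})

test_that("downsampling and direction averaging commute", {
  set.seed(5)
  vols <- lapply(1:6, function(i) array(rnorm(12 * 12 * 8), c(12, 12, 8)))
  a <- block_downsample(direction_average(vols), c(3, 3, 2))
  b <- direction_average(lapply(vols, block_downsample, factors = c(3, 3, 2)))
  expect_equal(a, b, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("b0 normalisation guards against unusable voxels", {
  b0 <- array(2, c(3, 3, 3))
  dwi <- b0 * 0.5
  out <- normalize_by_b0(dwi, b0)
  expect_equal(unique(as.vector(out)), 0.5)
  expect_true(all(attr(out, "valid")))
  b0[1, 1, 1] <- 0
  out <- normalize_by_b0(dwi, b0)
  expect_true(is.na(out[1, 1, 1]))
  expect_false(attr(out, "valid")[1, 1, 1])
  expect_equal(normalize_by_b0(b0, b0)[2, 2, 2], 1)
})

test_that("normalised noiseless phantom signals reproduce the linear mixture", {
  ph <- test_phantom()
  dmri <- simulate_dmri(ph)
  seqs <- steam_sequences()
  comp <- esldmri:::.component_signals(ph$config, seqs)
  fr <- dmri$fractions
  keep <- fr$f_U < 1          # some tissue or fluid present
  i <- 7
  avg <- direction_average(dmri$dwi[[i]])
  norm <- normalize_by_b0(avg, dmri$b0, floor = 1e-6)
  # renormalised fractions over (E, S, L) reproduce the mixture exactly
  tot <- fr$f_E + fr$f_S + fr$f_L
  pred <- (fr$f_E * comp$E[i] + fr$f_S * comp$S[i] + fr$f_L * comp$L[i]) / tot
  expect_lt(max(abs(norm[keep] - pred[keep])), 1e-12)
})

test_that("cylindrical ROI keeps only fully contained voxels", {
  m <- cylinder_roi(c(10, 10, 4), 100, radius_um = 1e6)
  expect_true(all(m))
  expect_warning(m0 <- cylinder_roi(c(10, 10, 4), 100, radius_um = 1e-3),
                 "no voxels")
  expect_false(any(m0))
  # voxels overlapping the phantom tube wall are excluded
  cfg <- test_phantom_config()
  dims <- c(6, 6, 8)
  vox <- 160
  m <- cylinder_roi(dims, vox, radius_um = cfg$tube_radius_um * 0.95)
  centre <- esldmri:::.centre_coords(6, vox)
  far <- sqrt(outer((abs(centre) + vox / 2)^2,
                    (abs(centre) + vox / 2)^2, "+"))
  expect_equal(m[, , 1], far <= cfg$tube_radius_um * 0.95)
})
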