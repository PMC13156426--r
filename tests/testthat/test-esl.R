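test_that("the fixed luminal signal is free diffusion at the medium diffusivity", {
  expect_equal(lumen_signal(0), 1)
  expect_equal(lumen_signal(1.0), exp(-2), tolerance = 1e-12)
  expect_equal(lumen_signal(2.0), exp(-4), tolerance = 1e-12)
  expect_error(lumen_signal(-1))
})

test_that("a determined two-voxel system is solved exactly", {
  fr <- data.frame(f_E = c(1, 0), f_S = c(0, 1), f_L = c(0, 0))
  fit <- fit_esl_sequence(c(0.4, 0.3), fr, b = 1)
  expect_equal(fit$s_e, 0.4, tolerance = 1e-12)
  expect_equal(fit$s_s, 0.3, tolerance = 1e-12)
})

test_that("pure-lumen voxels carry no information about tissue signals", {
  fr <- data.frame(f_E = c(1, 0, 0), f_S = c(0, 1, 0), f_L = c(0, 0, 1))
  s <- c(0.4, 0.3, lumen_signal(1.5))
  fit <- fit_esl_sequence(s, fr, b = 1.5)
  expect_equal(fit$s_e, 0.4, tolerance = 1e-12)
  expect_equal(fit$s_s, 0.3, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)
})

test_that("noiseless mixtures return the generating component signals", {
  set.seed(12)
  seqs <- steam_sequences()
  cfg <- phantom_config(noise_model = "none", sample_effect_sd = 0)
  comp <- esldmri:::.component_signals(cfg, seqs)
  g <- matrix(rgamma(60 * 3, shape = c(2.2, 4.6, 1.2)), 60, 3, byrow = TRUE)
  fr <- as.data.frame(g / rowSums(g))
  names(fr) <- c("f_E", "f_S", "f_L")
  sig <- as.matrix(fr) %*% rbind(comp$E, comp$S, comp$L)
  agg <- fit_esl_all(sig, fr, seqs)
  expect_equal(agg$s_e, comp$E, tolerance = 1e-10)
  expect_equal(agg$s_s, comp$S, tolerance = 1e-10)
  expect_true(all(agg$r2 > 1 - 1e-12))
})

test_that("the linear fit matches brute-force normal equations", {
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    fe <- runif(n); fs <- runif(n) * (1 - fe)
    fl <- 1 - fe - fs
    fr <- data.frame(f_E = fe, f_S = fs, f_L = fl)
    y <- runif(n)
    b <- 1.25
    fit <- fit_esl_sequence(y, fr, b)
    X <- cbind(fe, fs)
    yy <- y - fl * exp(-2 * b)
    beta <- solve(t(X) %*% X) %*% t(X) %*% yy
    expect_equal(c(fit$s_e, fit$s_s), as.vector(beta), tolerance = 1e-12)
  }
})

test_that("collinear designs fail loudly with a condition number", {
  fr <- data.frame(f_E = c(0.3, 0.3, 0.3), f_S = c(0.3, 0.3, 0.3),
                   f_L = c(0.4, 0.4, 0.4))
  expect_error(fit_esl_sequence(c(0.5, 0.5, 0.5), fr, 1), "condition number")
})

test_that("negative aggregate estimates warn and are not clipped", {
  fr <- data.frame(f_E = c(1, 0), f_S = c(0, 1), f_L = c(0, 0))
  expect_warning(fit <- fit_esl_sequence(c(-0.2, 0.3), fr, 1), "negative")
  expect_equal(fit$s_e, -0.2, tolerance = 1e-12)
})

test_that("observation preparation renormalises small unclassified fractions", {
  fr <- list(f_E = c(0.3, 0.3), f_S = c(0.5, 0.3), f_L = c(0.18, 0.2),
             f_U = c(0.02, 0.2))
  sig <- matrix(0.5, 2, 3)
  obs <- prepare_esl_observations(sig, fr, sample_id = c("a", "b"))
  expect_equal(obs$kept, c(TRUE, FALSE))   # f_U = 0.2 excluded
  expect_equal(rowSums(obs$fractions), 1, ignore_attr = TRUE)
  expect_equal(obs$sample_id, "a")
})

test_that("bootstrap uncertainty shrinks with information content", {
  set.seed(14)
  n <- 120
  fe <- runif(n); fs <- runif(n) * (1 - fe); fl <- 1 - fe - fs
  fr <- data.frame(f_E = fe, f_S = fs, f_L = fl)
  b <- 1.0
  noise_sd <- 0.02
  y <- 0.5 * fe + 0.35 * fs + fl * exp(-2) + rnorm(n, 0, noise_sd)
  bs1 <- bootstrap_esl(y, fr, b, n_boot = 800, seed = 1)
  # near-deterministic data: intervals collapse
  y0 <- 0.5 * fe + 0.35 * fs + fl * exp(-2)
  bs0 <- bootstrap_esl(y0, fr, b, n_boot = 400, seed = 1)
  expect_lt(diff(bs0$ci99[, "s_e"]), 1e-10)
  # doubling the voxel count shrinks the SE by about sqrt(2)
  fr2 <- rbind(fr, fr)
  y2 <- c(y, 0.5 * fe + 0.35 * fs + fl * exp(-2) + rnorm(n, 0, noise_sd))
  bs2 <- bootstrap_esl(y2, fr2, b, n_boot = 800, seed = 2)
  expect_equal(bs1$se[["s_e"]] / bs2$se[["s_e"]], sqrt(2), tolerance = 0.15)
  expect_identical(bootstrap_esl(y, fr, b, n_boot = 400, seed = 9)$se,
                   bootstrap_esl(y, fr, b, n_boot = 400, seed = 9)$se)
})

test_that("bootstrap SE matches the Monte-Carlo spread of estimates", {
  set.seed(15)
  n <- 80
  fe <- runif(n); fs <- runif(n) * (1 - fe); fl <- 1 - fe - fs
  fr <- data.frame(f_E = fe, f_S = fs, f_L = fl)
  b <- 1.0
  truth <- function() 0.5 * fe + 0.35 * fs + fl * exp(-2) +
    rnorm(n, 0, 0.03)
  mc <- replicate(200, fit_esl_sequence(truth(), fr, b)$s_e)
  bs <- bootstrap_esl(truth(), fr, b, n_boot = 1000, seed = 3)
  expect_equal(bs$se[["s_e"]], sd(mc), tolerance = 0.2 * sd(mc) / sd(mc) + 0.2)
  expect_lt(abs(bs$se[["s_e"]] - sd(mc)) / sd(mc), 0.25)
})

test_that("signal prediction is the exact weighted component sum", {
  seqs <- steam_sequences()
  agg <- data.frame(id = seqs$id, b = seqs$b,
                    s_e = seq(0.6, 0.4, length.out = 10),
                    s_s = seq(0.5, 0.25, length.out = 10))
  fr <- data.frame(f_E = c(1, 0, 0.3), f_S = c(0, 0, 0.5),
                   f_L = c(0, 1, 0.2))
  pred <- predict_signals(fr, agg, seqs)
  expect_equal(pred[1, ], agg$s_e, ignore_attr = TRUE)
  expect_equal(pred[2, ], lumen_signal(seqs$b), ignore_attr = TRUE)
  expect_equal(pred[3, 4],
               0.3 * agg$s_e[4] + 0.5 * agg$s_s[4] +
                 0.2 * lumen_signal(seqs$b[4]),
               ignore_attr = TRUE)
  expect_error(predict_signals(fr, agg[-1, ], seqs), "missing aggregate")
})

test_that("limits of differences behave like Bland-Altman bounds", {
  x <- c(1, 2, 3)
  lim <- limits_of_differences(x, x)
  expect_equal(lim$lower, 0)
  expect_equal(lim$upper, 0)
  set.seed(16)
  d <- rnorm(20000)
  lim <- limits_of_differences(d, rep(0, 20000))
  cover <- mean(d >= lim$lower & d <= lim$upper)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
  # a shifted group shows up in its median
  g <- rep(c("a", "b"), each = 50)
  m <- c(rnorm(50, 0, 0.01), rnorm(50, 0.5, 0.01))
  lim <- limits_of_differences(m, rep(0, 100), grouping = g)
  expect_equal(lim$by_group$median[lim$by_group$group == "b"], 0.5,
               tolerance = 0.02)
})
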