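# Per-sequence linear decomposition of voxel signals into aggregate
# epithelial and stromal contributions, with a fixed luminal signal,
# bootstrap uncertainty, signal prediction and limits of signal
# differences.

#' Fixed luminal/medium signal
#'
#' Free diffusion at the medium diffusivity (default 2.0 um^2/ms): the
#' luminal contribution is fixed during linear fitting because luminal
#' fluid equilibrates with the surrounding medium.
#'
#' @param b b-value(s), ms/um^2.
#' @param D diffusivity, um^2/ms.
#' @return exp(-b D).
#' @export
lumen_signal <- function(b, D = 2.0) {
  stopifnot(all(b >= 0))
  exp(-b * D)
}

#' Prepare voxel observations for linear ESL fitting
#'
#' Voxels with a small unclassified fraction (`f_U` below `f_u_max`) are
#' retained with (f_E, f_S, f_L) renormalised to sum to 1; voxels with
#' larger unclassified fractions, non-finite signals, or invalid
#' normalisation are excluded.
#'
#' @param signal matrix (voxels x sequences) of normalised signals, or a
#'   vector for a single sequence.
#' @param fractions data frame or list with `f_E`, `f_S`, `f_L` and
#'   optionally `f_U` per voxel (arrays are flattened).
#' @param sample_id optional per-voxel sample labels.
#' @param f_u_max maximum tolerated unclassified fraction (default 0.05).
#' @return List with `signal` matrix, `fractions` data frame, `sample_id`
#'   and the logical `kept` selector.
#' @export
prepare_esl_observations <- function(signal, fractions, sample_id = NULL,
                                     f_u_max = 0.05) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  fr <- data.frame(f_E = as.vector(fractions$f_E),
                   f_S = as.vector(fractions$f_S),
                   f_L = as.vector(fractions$f_L))
  f_u <- if (!is.null(fractions$f_U)) as.vector(fractions$f_U) else
    pmax(1 - rowSums(fr), 0)
  stopifnot(nrow(fr) == nrow(signal))
  keep <- f_u < f_u_max & rowSums(!is.finite(signal)) == 0 &
    rowSums(fr) > 0
  fr <- fr[keep, , drop = FALSE] / rowSums(fr[keep, , drop = FALSE])
  list(signal = signal[keep, , drop = FALSE], fractions = fr,
       sample_id = if (is.null(sample_id)) NULL else sample_id[keep],
       kept = keep)
}

#' Linear ESL decomposition for one dMRI sequence
#'
#' Ordinary least squares of the lumen-corrected signal
#' y_v = S_v - f_L,v * S_L(b) on the epithelial and stromal volume
#' fractions (two unknowns, no intercept), yielding aggregate component
#' signal estimates S_E and S_S for the sequence. The fit is unconstrained;
#' negative estimates are reported with a warning, never clipped. R^2 is
#' computed for the full three-component prediction against the
#' mean-of-y baseline.
#'
#' @param signal vector of normalised voxel signals for this sequence.
#' @param fractions data frame with `f_E`, `f_S`, `f_L` per voxel.
#' @param b the sequence b-value, ms/um^2.
#' @param lumen_d fixed luminal diffusivity, um^2/ms.
#' @param cond_max maximum tolerated design condition number.
#' @return List of class `esl_fit`: `s_e`, `s_s`, `r2`, `n_voxels`,
#'   `residuals`, `fitted`.
#' @export
fit_esl_sequence <- function(signal, fractions, b, lumen_d = 2.0,
                             cond_max = 1e8) {
  stopifnot(length(signal) == nrow(fractions), length(signal) >= 2)
  X <- cbind(f_E = fractions$f_E, f_S = fractions$f_S)
  y <- signal - fractions$f_L * lumen_signal(b, lumen_d)
  sv <- svd(X, nu = 0, nv = 0)$d
  kappa <- sv[1] / max(sv[2], .Machine$double.xmin)
  if (!is.finite(kappa) || kappa > cond_max)
    stop("singular design: epithelial and stromal fractions are collinear ",
         "(condition number ", format(kappa, digits = 3), ")")
  beta <- solve(crossprod(X), crossprod(X, y))
  if (any(beta < 0))
    warning("negative aggregate signal estimate (model misfit); not clipped")
  fitted_full <- X %*% beta + fractions$f_L * lumen_signal(b, lumen_d)
  resid <- signal - fitted_full
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(s_e = beta[1], s_s = beta[2], r2 = r2,
                 n_voxels = length(signal),
                 residuals = as.vector(resid),
                 fitted = as.vector(fitted_full)),
            class = "esl_fit")
}

#' Linear ESL decomposition for every sequence of a protocol
#'
#' @param signal matrix (voxels x sequences) of normalised signals, columns
#'   ordered as `sequences`.
#' @param fractions data frame with `f_E`, `f_S`, `f_L` per voxel.
#' @param sequences data frame of diffusion-weighted sequences (see
#'   [steam_sequences()]).
#' @param lumen_d fixed luminal diffusivity, um^2/ms.
#' @return Data frame with one row per sequence: `id`, `b`, `Delta`,
#'   `s_e`, `s_s`, `r2`, `n_voxels`.
#' @export
fit_esl_all <- function(signal, fractions, sequences, lumen_d = 2.0) {
  stopifnot(ncol(signal) == nrow(sequences))
  rows <- lapply(seq_len(nrow(sequences)), function(i) {
    f <- fit_esl_sequence(signal[, i], fractions, sequences$b[i], lumen_d)
    data.frame(id = sequences$id[i], b = sequences$b[i],
               Delta = sequences$Delta[i], s_e = f$s_e, s_s = f$s_s,
               r2 = f$r2, n_voxels = f$n_voxels)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap uncertainty for aggregate ESL signal estimates
#'
#' Voxel-level resampling with replacement: signals and their volume
#' fractions are resampled together and the linear model refit per
#' replicate. Standard errors are the SD of replicate estimates; confidence
#' intervals are the 0.5th-99.5th percentile interval (99%). Replicates
#' with a singular design are skipped and counted.
#'
#' @param signal vector of voxel signals for one sequence.
#' @param fractions data frame with `f_E`, `f_S`, `f_L`.
#' @param b sequence b-value, ms/um^2.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer seed (resampling is deterministic given it).
#' @param lumen_d fixed luminal diffusivity.
#' @return List: `se` (named, for S_E and S_S), `ci99` (2 x 2 matrix),
#'   `n_boot_used`, `n_skipped`, and the replicate `estimates` matrix.
#' @export
bootstrap_esl <- function(signal, fractions, b, n_boot = 10000, seed = 1L,
                          lumen_d = 2.0) {
  stopifnot(n_boot >= 100)
  set.seed(seed)
  n <- length(signal)
  fe <- fractions$f_E; fs <- fractions$f_S
  y <- signal - fractions$f_L * lumen_signal(b, lumen_d)
  est <- matrix(NA_real_, n_boot, 2)
  skipped <- 0L
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    e <- fe[idx]; s <- fs[idx]; yy <- y[idx]
    a11 <- sum(e * e); a12 <- sum(e * s); a22 <- sum(s * s)
    det <- a11 * a22 - a12^2
    if (det <= 1e-12 * a11 * a22 || !is.finite(det) || det == 0) {
      skipped <- skipped + 1L
      next
    }
    b1 <- sum(e * yy); b2 <- sum(s * yy)
    est[r, ] <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
  }
  ok <- stats::complete.cases(est)
  est_ok <- est[ok, , drop = FALSE]
  se <- apply(est_ok, 2, stats::sd)
  ci <- apply(est_ok, 2, stats::quantile, probs = c(0.005, 0.995))
  colnames(ci) <- c("s_e", "s_s")
  names(se) <- c("s_e", "s_s")
  list(se = se, ci99 = ci, n_boot_used = sum(ok), n_skipped = skipped,
       estimates = est_ok)
}

#' Predicted voxel signals from aggregate component estimates
#'
#' The three-component prediction: for every voxel and sequence,
#' f_E * S_E + f_S * S_S + f_L * S_L(b).
#'
#' @param fractions data frame with `f_E`, `f_S`, `f_L` per voxel.
#' @param aggregates data frame from [fit_esl_all()] (columns `id`, `b`,
#'   `s_e`, `s_s`), one row per sequence.
#' @param sequences sequence table; every sequence must have an aggregate
#'   row.
#' @param lumen_d fixed luminal diffusivity.
#' @return Matrix (voxels x sequences) of predicted signals.
#' @export
predict_signals <- function(fractions, aggregates,
                            sequences = NULL, lumen_d = 2.0) {
  if (is.null(sequences)) sequences <- aggregates
  m <- match(sequences$id, aggregates$id)
  if (anyNA(m))
    stop("missing aggregate estimates for sequence(s): ",
         paste(sequences$id[is.na(m)], collapse = ", "))
  s_e <- aggregates$s_e[m]; s_s <- aggregates$s_s[m]
  s_l <- lumen_signal(sequences$b, lumen_d)
  out <- as.matrix(fractions$f_E) %*% s_e +
    as.matrix(fractions$f_S) %*% s_s +
    as.matrix(fractions$f_L) %*% s_l
  colnames(out) <- sequences$id
  out
}

#' 95% limits of paired differences
#'
#' Bland-Altman-style agreement bounds: mean +/- 1.96 SD of the paired
#' differences (measured - predicted), with optional per-group boxplot
#' statistics.
#'
#' @param measured,predicted paired numeric vectors (or matrices flattened
#'   in parallel).
#' @param grouping optional per-value group labels (e.g. sample ids).
#' @return List of class `difference_limits`: `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `n`, and `by_group` (data frame of median/quartiles
#'   per group, when grouping is given).
#' @export
limits_of_differences <- function(measured, predicted, grouping = NULL) {
  d <- as.vector(measured) - as.vector(predicted)
  ok <- is.finite(d)
  d <- d[ok]
  m <- mean(d)
  s <- stats::sd(d)
  by_group <- NULL
  if (!is.null(grouping)) {
    g <- rep_len(as.vector(grouping), length(ok))[ok]
    stats_g <- tapply(d, g, function(v)
      c(n = length(v), median = stats::median(v),
        q1 = unname(stats::quantile(v, 0.25)),
        q3 = unname(stats::quantile(v, 0.75))))
    by_group <- data.frame(group = names(stats_g),
                           do.call(rbind, stats_g), row.names = NULL)
  }
  structure(list(mean_diff = m, sd_diff = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s,
                 n = length(d), by_group = by_group),
            class = "difference_limits")
}

#' @export
print.difference_limits <- function(x, ...) {
  cat(sprintf("95%% limits of differences: %.4g +/- 1.96 x %.4g -> [%.4g, %.4g]  (n = %d)\n",
              x$mean_diff, x$sd_diff, x$lower, x$upper, x$n))
  invisible(x)
}
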