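# Voxelwise model fitting on measured and predicted signal profiles,
# 95% limits of parameter differences in benign tissue, and evaluation of
# cancer voxels against those limits.

# Parameters whose differences are tracked per model.
.tracked_params <- list(adc = "D",
                        ballsphere = c("f_sphere", "D_ball", "R"))

#' Fit models voxelwise to measured and predicted signal profiles
#'
#' For each voxel, each requested model is fit (via [fit_model()]) to both
#' the measured and the predicted profile, and per-parameter differences
#' (measured - predicted) are recorded. Differences are defined only where
#' both fits converged; bound-pegged estimates are flagged.
#'
#' @param measured,predicted matrices (voxels x sequences) of signal
#'   profiles sharing voxel order.
#' @param sequences sequence table matching the columns.
#' @param models models to fit (default ADC and ball+sphere).
#' @param sample_id optional per-voxel sample labels.
#' @param starts named list of start grids passed to [fit_model()] per
#'   model. The default uses a reduced deterministic 4-start grid per model
#'   (a subset of the full aggregate-fit grid) for throughput across many
#'   voxels; measured and predicted profiles always share the same starts.
#' @return Data frame of class `voxel_fit_pairs`, one row per
#'   voxel x model x tracked parameter: `voxel`, `sample_id`, `model`,
#'   `parameter`, `measured`, `predicted`, `diff`, `converged`,
#'   `at_bound`.
#' @export
fit_voxelwise <- function(measured, predicted, sequences,
                          models = c("adc", "ballsphere"),
                          sample_id = NULL, starts = NULL) {
  stopifnot(all(dim(measured) == dim(predicted)))
  if (is.null(starts))
    starts <- list(
      adc = cbind(S0 = 1, D = c(0.3, 0.8, 1.5, 2.4)),
      ballsphere = .model_starts("ballsphere")[c(1, 4, 6, 7), , drop = FALSE])
  nv <- nrow(measured)
  if (is.null(sample_id)) sample_id <- rep(NA_character_, nv)
  rows <- vector("list", nv * length(models))
  ri <- 0L
  for (v in seq_len(nv)) {
    for (mod in models) {
      st <- if (!is.null(starts)) starts[[mod]] else NULL
      fm <- fit_model(measured[v, ], sequences, mod, starts = st,
                      compute_se = FALSE)
      fp <- fit_model(predicted[v, ], sequences, mod, starts = st,
                      compute_se = FALSE)
      pars <- .tracked_params[[mod]]
      conv <- fm$converged && fp$converged
      bound <- if (conv) fm$at_bound[pars] | fp$at_bound[pars] else
        rep(NA, length(pars))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        voxel = v, sample_id = sample_id[v], model = mod, parameter = pars,
        measured = if (conv) unname(fm$params[pars]) else NA_real_,
        predicted = if (conv) unname(fp$params[pars]) else NA_real_,
        diff = if (conv) unname(fm$params[pars] - fp$params[pars]) else
          NA_real_,
        converged = conv, at_bound = unname(bound),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  class(out) <- c("voxel_fit_pairs", "data.frame")
  out
}

#' 95% limits of parameter differences in benign tissue
#'
#' Pooled across all benign voxels: mean +/- 1.96 SD of the per-voxel
#' parameter differences for each tracked parameter. Non-converged and
#' bound-pegged fits are excluded from the limits but counted.
#'
#' @param pairs a `voxel_fit_pairs` data frame from [fit_voxelwise()].
#' @param min_n minimum number of usable voxels per parameter.
#' @return Data frame: `model`, `parameter`, `mean_diff`, `sd_diff`,
#'   `lower`, `upper`, `n_used`, `n_excluded`.
#' @export
parameter_limits <- function(pairs, min_n = 30) {
  key <- interaction(pairs$model, pairs$parameter, drop = TRUE)
  rows <- lapply(split(pairs, key), function(pp) {
    use <- pp$converged & !pp$at_bound & is.finite(pp$diff)
    n <- sum(use)
    if (n < min_n)
      stop("too few usable voxels for ", pp$model[1], ":", pp$parameter[1],
           " (", n, " < ", min_n, ")")
    d <- pp$diff[use]
    m <- mean(d); s <- stats::sd(d)
    data.frame(model = pp$model[1], parameter = pp$parameter[1],
               mean_diff = m, sd_diff = s,
               lower = m - 1.96 * s, upper = m + 1.96 * s,
               n_used = n, n_excluded = nrow(pp) - n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a cancer cohort against benign parameter-difference limits
#'
#' For each tracked parameter, reports the fraction (and identity) of
#' cancer voxels whose measured-minus-predicted parameter difference falls
#' outside the 95% limits established in benign tissue, controlling for
#' voxel composition through the predicted-profile baseline.
#'
#' @param pairs a `voxel_fit_pairs` data frame for the cancer voxels.
#' @param limits data frame from [parameter_limits()] (benign tissue).
#' @return Data frame of class `cohort_comparison`: `model`, `parameter`,
#'   `n`, `fraction_outside`, `median_diff`, plus attribute
#'   `outside_voxels` (named list of voxel ids outside the limits).
#' @export
compare_cohort <- function(pairs, limits) {
  out_list <- list()
  rows <- lapply(seq_len(nrow(limits)), function(i) {
    li <- limits[i, ]
    pp <- pairs[pairs$model == li$model & pairs$parameter == li$parameter &
                  pairs$converged & is.finite(pairs$diff), , drop = FALSE]
    n <- nrow(pp)
    outside <- pp$diff < li$lower | pp$diff > li$upper
    out_list[[paste(li$model, li$parameter, sep = ":")]] <<-
      pp$voxel[outside]
    data.frame(model = li$model, parameter = li$parameter, n = n,
               fraction_outside = if (n > 0) mean(outside) else NA_real_,
               median_diff = if (n > 0) stats::median(pp$diff) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outside_voxels") <- out_list
  class(out) <- c("cohort_comparison", "data.frame")
  out
}
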