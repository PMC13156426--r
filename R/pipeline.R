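# End-to-end orchestration: phantom simulation (or ingested volumes),
# preprocessing, segmentation, volume fractions, linear ESL decomposition,
# aggregate model fitting, voxelwise analysis and report files.

#' Pipeline configuration
#'
#' @param phantom a [phantom_config()] describing the synthetic dataset to
#'   analyse.
#' @param segmentation a [segmentation_config()].
#' @param out_dir output directory for report files (created if missing);
#'   `NULL` suppresses file output.
#' @param n_boot bootstrap replicates for aggregate-signal uncertainty
#'   (default 10000); 0 disables bootstrapping.
#' @param seed seed for bootstrap resampling.
#' @param downsample_factors per-axis block sizes applied to the
#'   direction-averaged dMRI volumes (default 3 x 3 x 2, i.e. 160 um ->
#'   480 x 480 x 320 um voxels).
#' @param roi_radius_um analysis cylinder radius; default 95% of the tube
#'   radius, so voxels overlapping the tube wall are excluded.
#' @param denoise whether to MP-PCA denoise the DTI and dMRI stacks.
#' @param voxelwise whether to run the voxelwise measured-vs-predicted
#'   model comparison.
#' @param models models for the aggregate profile fits.
#' @param f_u_max unclassified-fraction cutoff for voxel retention.
#' @param fractions_source `"segmentation"` (default) derives ESL volume
#'   fractions from the simulated microscopy images via the threshold
#'   segmentation; `"truth"` uses the phantom's ground-truth labels
#'   directly (a validation mode that isolates the dMRI signal chain from
#'   segmentation error).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            segmentation = segmentation_config(),
                            out_dir = NULL,
                            n_boot = 10000, seed = 1L,
                            downsample_factors = c(3, 3, 2),
                            roi_radius_um = NULL,
                            denoise = TRUE,
                            voxelwise = TRUE,
                            models = c("adc", "dki", "sphere", "ballsphere"),
                            f_u_max = 0.05,
                            fractions_source = c("segmentation", "truth")) {
  fractions_source <- match.arg(fractions_source)
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(segmentation, "segmentation_config"))
  if (is.null(roi_radius_um)) roi_radius_um <- 0.95 * phantom$tube_radius_um
  structure(list(phantom = phantom, segmentation = segmentation,
                 out_dir = out_dir, n_boot = n_boot, seed = as.integer(seed),
                 downsample_factors = as.integer(downsample_factors),
                 roi_radius_um = roi_radius_um, denoise = denoise,
                 voxelwise = voxelwise, models = models, f_u_max = f_u_max,
                 fractions_source = fractions_source),
            class = "pipeline_config")
}

# Ring-shaped medium reference mask between the tissue core and tube wall.
.medium_reference_mask <- function(cfg) {
  dims <- cfg$grid_shape
  h <- cfg$voxel_um
  x <- .centre_coords(dims[1], h)
  y <- .centre_coords(dims[2], h)
  r2 <- outer(x^2, y^2, "+")
  margin <- min(3 * h, (cfg$tube_radius_um - cfg$tissue_radius_um) / 3)
  inner <- cfg$tissue_radius_um + margin
  outer_r <- cfg$tube_radius_um - margin
  ring <- r2 > inner^2 & r2 < outer_r^2
  array(rep(ring, dims[3]), dims)
}

.log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a phantom with its microscopy and dMRI acquisitions, then
#' runs preprocessing, ESL segmentation, volume-fraction computation,
#' per-sequence linear decomposition with bootstrap uncertainty, aggregate
#' model fitting with AICc ranking, and (optionally) the voxelwise
#' measured-vs-predicted comparison. Writes CSV/JSON report files plus a
#' run manifest when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @param verbose log one line per stage with shapes and voxel counts.
#' @return List of class `pipeline_result`: `phantom`, `fractions`,
#'   `labels`, `aggregates` (per-sequence estimates with bootstrap SEs and
#'   99% CIs), `aggregate_fits` (per model x component), `signal_limits`,
#'   `voxel_pairs`, `parameter_limits`, `manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  pcfg <- config$phantom
  protocol <- canonical_protocol()
  seqs <- steam_sequences(protocol)

  phantom <- generate_phantom(pcfg)
  .log_stage(verbose, "simulate", "phantom %s, fractions E/S/L/M = %s",
             paste(dim(phantom$labels), collapse = "x"),
             paste(signif(phantom$fractions, 3), collapse = "/"))
  dmri <- simulate_dmri(phantom, protocol, pcfg)

  # --- microscopy segmentation (or ground-truth labels) ---
  if (config$fractions_source == "truth") {
    labels <- phantom$labels
  } else {
    gre <- simulate_gre(phantom, pcfg)
    dti <- simulate_dti(phantom, pcfg)
    gre_avg <- average_echoes(gre)
    medium_mask <- .medium_reference_mask(pcfg)
    la <- segment_lumen_air(gre_avg, medium_mask, config$segmentation)
    dti_proc <- dti
    if (config$denoise) {
      den <- mppca_denoise(c(dti$b0, dti$dwi))
      nb0 <- length(dti$b0)
      dti_proc$b0 <- lapply(seq_len(nb0), function(i) den$denoised[, , , i])
      dti_proc$dwi <- lapply(seq_along(dti$dwi), function(i)
        den$denoised[, , , nb0 + i])
    }
    up <- function(v) upsample_linear(v, dti$voxel_um, phantom$voxel_um)
    dti_hi <- list(b0 = lapply(dti_proc$b0, up),
                   dwi = lapply(dti_proc$dwi, up),
                   b = dti$b, directions = dti$directions,
                   voxel_um = phantom$voxel_um)
    tensor <- fit_dti(dti_hi)
    stroma <- segment_stroma(tensor, config$segmentation,
                             exclude = la$lumen | la$air)
    labels <- compose_esl(la$lumen, stroma, la$air)
  }
  low_res_um <- dmri$voxel_um * config$downsample_factors
  fractions <- volume_fractions(labels, phantom$voxel_um, low_res_um)
  .log_stage(verbose, "segment",
             "labels %s; mean fractions E/S/L/U = %s",
             paste(dim(labels), collapse = "x"),
             paste(signif(c(mean(fractions$f_E), mean(fractions$f_S),
                            mean(fractions$f_L), mean(fractions$f_U)), 3),
                   collapse = "/"))

  # --- dMRI preprocessing ---
  dmri_vols <- c(list(dmri$b0), unlist(dmri$dwi, recursive = FALSE))
  if (config$denoise) {
    den <- mppca_denoise(dmri_vols)
    dmri_vols <- lapply(seq_len(dim(den$denoised)[4]), function(i)
      den$denoised[, , , i])
  }
  b0_low <- block_downsample(dmri_vols[[1]], config$downsample_factors)
  nd <- seqs$n_directions[1]
  norm <- matrix(NA_real_, length(b0_low), nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    vols <- dmri_vols[1 + ((i - 1) * nd + 1):(i * nd)]
    avg <- direction_average(vols, nd)
    low <- block_downsample(avg, config$downsample_factors)
    nn <- normalize_by_b0(low, b0_low)
    norm[, i] <- as.vector(nn)
  }
  colnames(norm) <- seqs$id
  roi <- cylinder_roi(dim(b0_low), low_res_um, config$roi_radius_um)
  .log_stage(verbose, "preprocess", "low-res grid %s; ROI voxels %d",
             paste(dim(b0_low), collapse = "x"), sum(roi))

  # --- linear ESL decomposition ---
  fr_roi <- lapply(fractions[c("f_E", "f_S", "f_L", "f_U")],
                   function(a) as.vector(a)[as.vector(roi)])
  sig_roi <- norm[as.vector(roi), , drop = FALSE]
  obs <- prepare_esl_observations(sig_roi, fr_roi, f_u_max = config$f_u_max)
  .log_stage(verbose, "fit-esl", "voxels used %d of %d in ROI",
             nrow(obs$signal), sum(roi))
  aggregates <- fit_esl_all(obs$signal, obs$fractions, seqs,
                            lumen_d = pcfg$component_params$lumen_d)
  if (config$n_boot > 0) {
    bs <- lapply(seq_len(nrow(seqs)), function(i)
      bootstrap_esl(obs$signal[, i], obs$fractions, seqs$b[i],
                    n_boot = config$n_boot, seed = config$seed + i,
                    lumen_d = pcfg$component_params$lumen_d))
    aggregates$se_e <- vapply(bs, function(x) x$se["s_e"], numeric(1))
    aggregates$se_s <- vapply(bs, function(x) x$se["s_s"], numeric(1))
    aggregates$ci99_e_lo <- vapply(bs, function(x) x$ci99[1, "s_e"], numeric(1))
    aggregates$ci99_e_hi <- vapply(bs, function(x) x$ci99[2, "s_e"], numeric(1))
    aggregates$ci99_s_lo <- vapply(bs, function(x) x$ci99[1, "s_s"], numeric(1))
    aggregates$ci99_s_hi <- vapply(bs, function(x) x$ci99[2, "s_s"], numeric(1))
  }

  predicted <- predict_signals(obs$fractions, aggregates, seqs,
                               lumen_d = pcfg$component_params$lumen_d)
  signal_limits <- limits_of_differences(obs$signal, predicted)

  # --- aggregate model fitting ---
  fit_rows <- list()
  for (compn in c("epithelium", "stroma")) {
    prof <- if (compn == "epithelium") aggregates$s_e else aggregates$s_s
    for (mod in config$models) {
      ft <- fit_model(prof, seqs, mod)
      fit_rows[[paste(compn, mod)]] <- data.frame(
        component = compn, model = mod,
        parameter = names(ft$params), estimate = unname(ft$params),
        se = if (is.null(ft$se)) NA_real_ else unname(ft$se),
        rss = ft$rss, aicc = ft$aicc, converged = ft$converged,
        stringsAsFactors = FALSE)
    }
  }
  aggregate_fits <- do.call(rbind, fit_rows)
  rownames(aggregate_fits) <- NULL

  voxel_pairs <- NULL
  par_limits <- NULL
  if (config$voxelwise) {
    voxel_pairs <- fit_voxelwise(obs$signal, predicted, seqs)
    par_limits <- tryCatch(parameter_limits(voxel_pairs),
                           error = function(e) {
                             warning(conditionMessage(e))
                             NULL
                           })
    .log_stage(verbose, "voxelwise", "fitted %d voxels",
               nrow(obs$signal))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("esldmri")),
    seed = config$seed, phantom_seed = pcfg$seed,
    config_hash = config_hash(unclass(config)[setdiff(names(unclass(config)),
                                                      "out_dir")]),
    grid_shape = pcfg$grid_shape, low_res_um = low_res_um,
    n_roi_voxels = sum(roi), n_voxels_used = nrow(obs$signal),
    mean_fractions = c(f_E = mean(fr_roi$f_E), f_S = mean(fr_roi$f_S),
                       f_L = mean(fr_roi$f_L), f_U = mean(fr_roi$f_U)))

  result <- structure(list(phantom = phantom, fractions = fractions,
                           labels = labels, observations = obs,
                           aggregates = aggregates,
                           aggregate_fits = aggregate_fits,
                           predicted = predicted,
                           signal_limits = signal_limits,
                           voxel_pairs = voxel_pairs,
                           parameter_limits = par_limits,
                           manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {
      df$config_hash <- manifest$config_hash
      df$seed <- config$seed
      df
    }
    utils::write.csv(stamp(aggregates),
                     file.path(config$out_dir, "aggregates.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(aggregate_fits),
                     file.path(config$out_dir, "aggregate_fits.csv"),
                     row.names = FALSE)
    if (!is.null(voxel_pairs))
      utils::write.csv(stamp(voxel_pairs),
                       file.path(config$out_dir, "voxelwise.csv"),
                       row.names = FALSE)
    if (!is.null(par_limits))
      utils::write.csv(stamp(par_limits),
                       file.path(config$out_dir, "parameter_limits.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(limits = list(mean_diff = signal_limits$mean_diff,
                         sd_diff = signal_limits$sd_diff,
                         lower = signal_limits$lower,
                         upper = signal_limits$upper),
           manifest = manifest),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_volume(array(as.numeric(labels), dim(labels)),
                 file.path(config$out_dir, "esl_labels.nii.gz"),
                 voxel_um = phantom$voxel_um)
    frac4d <- array(c(fractions$f_E, fractions$f_S, fractions$f_L,
                      fractions$f_U), c(dim(fractions$f_E), 4))
    write_volume(frac4d, file.path(config$out_dir, "fractions.nii.gz"),
                 voxel_um = low_res_um)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("ESL dMRI pipeline result\n")
  cat(sprintf("  voxels analysed: %d (ROI %d)\n",
              x$manifest$n_voxels_used, x$manifest$n_roi_voxels))
  cat(sprintf("  mean fractions E/S/L/U: %s\n",
              paste(signif(x$manifest$mean_fractions, 3), collapse = "/")))
  cat("  aggregate-fit AICc by model:\n")
  tab <- unique(x$aggregate_fits[, c("component", "model", "aicc")])
  print(tab, row.names = FALSE)
  invisible(x)
}
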