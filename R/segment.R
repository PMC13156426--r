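# Microstructure segmentation at microscopy resolution: gradient-echo
# compositing, diffusion tensor fitting, lumen/air thresholds, the
# diffusivity-weighted-anisotropy stroma criterion, and low-resolution
# volume fractions.

#' Segmentation thresholds
#'
#' @param lumen_threshold_value lumen/fluid threshold as a fraction of the
#'   median medium intensity (default 0.8); voxels at or above
#'   `lumen_threshold_value * median(medium)` are classified lumen/fluid.
#' @param air_min_threshold absolute minimum intensity below which voxels
#'   are treated as signal voids (air bubbles) and left unclassified.
#' @param dfa_threshold_mm2_s stroma cutoff on the product of mean
#'   diffusivity and fractional anisotropy, in mm^2/s (default 1.4e-4,
#'   i.e. 0.14 um^2/ms internally).
#' @return List of class `segmentation_config`.
#' @export
segmentation_config <- function(lumen_threshold_value = 0.8,
                                air_min_threshold = 0.2,
                                dfa_threshold_mm2_s = 1.4e-4) {
  stopifnot(lumen_threshold_value > 0, lumen_threshold_value < 1,
            dfa_threshold_mm2_s > 0)
  structure(list(lumen_threshold_value = lumen_threshold_value,
                 air_min_threshold = air_min_threshold,
                 dfa_threshold_mm2_s = dfa_threshold_mm2_s),
            class = "segmentation_config")
}

#' Average multi-gradient-echo images into one gradient-echo image
#'
#' @param mge an `esl_gre` object or list of echo volumes (>= 2).
#' @return Voxelwise mean across echoes.
#' @export
average_echoes <- function(mge) {
  echoes <- if (inherits(mge, "esl_gre")) mge$echoes else mge
  if (length(echoes) < 2) stop("need at least 2 echoes")
  d <- dim(echoes[[1]])
  if (!all(vapply(echoes, function(e) all(dim(e) == d), logical(1))))
    stop("echo volumes have mismatched shapes")
  direction_average(echoes)
}

#' Segment lumen/fluid and air from the gradient-echo image
#'
#' Bright voxels (relatively long T2: luminal space, larger fluid regions
#' and the surrounding medium) are classified lumen/fluid using a threshold
#' derived from the medium intensities; signal voids below an absolute
#' minimum threshold are flagged unclassified (air bubbles).
#'
#' @param gre gradient-echo volume (output of [average_echoes()]).
#' @param medium logical mask of the medium reference region, or a numeric
#'   vector of medium intensities.
#' @param config a [segmentation_config()].
#' @return List with logical arrays `lumen`, `air` and the numeric
#'   `thresholds` used.
#' @export
segment_lumen_air <- function(gre, medium, config = segmentation_config()) {
  vals <- if (is.logical(medium)) gre[medium] else as.numeric(medium)
  if (length(vals) == 0) stop("medium reference region is empty")
  if (stats::sd(vals) == 0)
    warning("degenerate medium statistics (zero spread); proceeding")
  lumen_thr <- config$lumen_threshold_value * stats::median(vals)
  air_thr <- config$air_min_threshold
  lumen <- gre >= lumen_thr
  air <- gre <= air_thr
  lumen[air] <- FALSE
  list(lumen = lumen, air = air,
       thresholds = c(lumen = lumen_thr, air = air_thr))
}

# Vectorised eigenvalues of symmetric 3x3 tensors (Cardano), columns
# ascending; inputs are vectors of the six unique elements.
.eig_sym3 <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < 1e-14 * pmax(abs(q), 1e-30)
  ps <- ifelse(iso, 1, p)
  bxx <- (xx - q) / ps; byy <- (yy - q) / ps; bzz <- (zz - q) / ps
  bxy <- xy / ps; bxz <- xz / ps; byz <- yz / ps
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  cbind(l3, l2, l1)
}

#' Log-linear diffusion tensor fit
#'
#' Per-voxel ordinary least squares on log signals with seven unknowns
#' (log S0 and the six tensor elements). Mean diffusivity is the eigenvalue
#' mean and fractional anisotropy uses the standard eigenvalue formula;
#' negative eigenvalues are clamped to zero before both, with the voxel's
#' `valid` flag retained. Voxels with non-positive signals are marked
#' invalid.
#'
#' @param dti an `esl_dti` object, or a list with elements `b0` (list of
#'   volumes), `dwi` (list of direction volumes), `b` (ms/um^2) and
#'   `directions` (n x 3 unit vectors).
#' @return List of class `tensor_maps`: `md` (um^2/ms), `fa`, `valid`,
#'   `tensor` (V x 6 matrix of Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `voxel_um`.
#' @export
fit_dti <- function(dti) {
  b0s <- dti$b0; dwis <- dti$dwi
  b <- dti$b; dirs <- dti$directions
  if (length(b0s) < 1 || nrow(dirs) < 6)
    stop("need >= 1 b0 volume and >= 6 encoding directions")
  d <- dim(b0s[[1]])
  vols <- c(b0s, dwis)
  nv <- length(vols)
  A <- matrix(0, nv, 7)
  A[, 1] <- 1
  for (i in seq_along(dwis)) {
    g <- dirs[i, ]
    A[length(b0s) + i, 2:7] <-
      -b * c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3],
             2 * g[2] * g[3])
  }
  if (qr(A)$rank < 7) stop("encoding directions are collinear")
  pinv <- solve(crossprod(A), t(A))
  S <- matrix(unlist(vols, use.names = FALSE), prod(d), nv)
  valid <- rowSums(S <= 0 | !is.finite(S)) == 0
  logS <- matrix(0, prod(d), nv)
  logS[valid, ] <- log(S[valid, , drop = FALSE])
  coef <- logS %*% t(pinv)                 # V x 7
  ev <- .eig_sym3(coef[, 2], coef[, 3], coef[, 4], coef[, 5], coef[, 6],
                  coef[, 7])
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- rowSums(ev^2)
  fa <- sqrt(1.5 * num / pmax(den, 1e-30))
  fa[den <= 0] <- 0
  md[!valid] <- NA_real_
  fa[!valid] <- NA_real_
  structure(list(md = array(md, d), fa = array(fa, d),
                 valid = array(valid, d),
                 tensor = coef[, 2:7, drop = FALSE],
                 voxel_um = dti$voxel_um),
            class = "tensor_maps")
}

#' Trilinear upsampling to a finer grid
#'
#' Voxel-centre-aligned trilinear interpolation: both grids share the same
#' physical extent with centres at (i - 1/2) * voxel size; border targets
#' beyond the outermost source centres are clamped.
#'
#' @param volume 3D array at the source resolution.
#' @param voxel_um source voxel edge (scalar or length 3), um.
#' @param target_um target voxel edge (finer than source), um.
#' @return Interpolated array at the target resolution.
#' @export
upsample_linear <- function(volume, voxel_um, target_um) {
  voxel_um <- rep_len(voxel_um, 3)
  target_um <- rep_len(target_um, 3)
  if (any(target_um > voxel_um))
    stop("target resolution must be finer than source")
  d <- dim(volume)
  d_t <- as.integer(round(d * voxel_um / target_um))
  idx <- function(n_t, h_t, h_s, n_s) {
    pos <- (seq_len(n_t) - 0.5) * h_t
    u <- pos / h_s + 0.5            # fractional source index
    i0 <- pmin(pmax(floor(u), 1), n_s - 1)
    w <- pmin(pmax(u - i0, 0), 1)
    list(i0 = as.integer(i0), i1 = as.integer(i0 + 1), w = w)
  }
  ax <- lapply(1:3, function(a) idx(d_t[a], target_um[a], voxel_um[a], d[a]))
  v <- volume[ax[[1]]$i0, , , drop = FALSE] * (1 - ax[[1]]$w) +
    volume[ax[[1]]$i1, , , drop = FALSE] * ax[[1]]$w
  v <- sweep(v[, ax[[2]]$i0, , drop = FALSE], 2, 1 - ax[[2]]$w, "*") +
    sweep(v[, ax[[2]]$i1, , drop = FALSE], 2, ax[[2]]$w, "*")
  v <- sweep(v[, , ax[[3]]$i0, drop = FALSE], 3, 1 - ax[[3]]$w, "*") +
    sweep(v[, , ax[[3]]$i1, drop = FALSE], 3, ax[[3]]$w, "*")
  v
}

#' Segment stroma from tensor maps
#'
#' Stroma has higher diffusivity and anisotropy than epithelium; voxels
#' whose product of mean diffusivity and fractional anisotropy exceeds the
#' configured cutoff (default 1.4e-4 mm^2/s) are classified stroma, unless
#' already claimed by the lumen/air masks.
#'
#' @param tensor a `tensor_maps` object from [fit_dti()] (at microscopy
#'   resolution).
#' @param config a [segmentation_config()].
#' @param exclude optional logical array of voxels to exclude (e.g. lumen
#'   or air).
#' @return Logical stroma mask.
#' @export
segment_stroma <- function(tensor, config = segmentation_config(),
                           exclude = NULL) {
  thr <- diffusivity_to_internal(config$dfa_threshold_mm2_s)
  dfa <- tensor$md * tensor$fa
  mask <- !is.na(dfa) & dfa > thr & tensor$valid
  if (!is.null(exclude)) mask <- mask & !exclude
  mask
}

#' Compose the epithelium/stroma/lumen label volume
#'
#' Precedence: lumen and air claims first, then stroma, and all remaining
#' tissue is epithelium. Voxels outside the region of interest are left
#' unclassified (coded as air).
#'
#' @param lumen,stroma,air logical masks at microscopy resolution.
#' @param roi optional logical mask restricting the labeling.
#' @return Integer label array per [esl_labels()] (unclassified voxels get
#'   the `air` code).
#' @export
compose_esl <- function(lumen, stroma, air, roi = NULL) {
  L <- esl_labels()
  d <- dim(lumen)
  labels <- array(L["epithelium"], d)
  labels[stroma] <- L["stroma"]
  labels[lumen] <- L["lumen"]
  labels[air] <- L["air"]
  if (!is.null(roi)) labels[!roi] <- L["air"]
  labels
}

#' Volume fractions of tissue components in low-resolution voxels
#'
#' Per low-resolution voxel, the fraction of microscopy-resolution label
#' voxels in each class: epithelium (`f_E`), stroma (`f_S`), lumen/fluid
#' including medium (`f_L`), and unclassified (`f_U`). Fractions sum to 1.
#'
#' @param labels integer label array per [esl_labels()].
#' @param voxel_um microscopy voxel edge, um.
#' @param low_res_um low-resolution voxel edges (scalar or length 3), um;
#'   each must be an integer multiple of `voxel_um`.
#' @return List of class `fraction_maps` with arrays `f_E`, `f_S`, `f_L`,
#'   `f_U` and `voxel_um` (the low-resolution edges).
#' @export
volume_fractions <- function(labels, voxel_um, low_res_um) {
  low_res_um <- rep_len(low_res_um, 3)
  f <- low_res_um / voxel_um
  if (any(abs(f - round(f)) > 1e-9))
    stop("low-resolution voxel edges must be integer multiples of ",
         voxel_um, " um")
  f <- as.integer(round(f))
  L <- esl_labels()
  ind <- function(classes) {
    .block_mean(array(as.numeric(labels %in% classes), dim(labels)), f)
  }
  structure(list(f_E = ind(L["epithelium"]), f_S = ind(L["stroma"]),
                 f_L = ind(c(L["lumen"], L["medium"])),
                 f_U = ind(L["air"]), voxel_um = low_res_um),
            class = "fraction_maps")
}

#' Sensitivity of segmentations to threshold choices
#'
#' Recomputes the segmentation over a grid of lumen-threshold and
#' D*FA-threshold settings around the configured values and reports the
#' global mean component fractions per setting.
#'
#' @param gre gradient-echo volume.
#' @param tensor `tensor_maps` at microscopy resolution.
#' @param medium medium reference (mask or intensities).
#' @param config baseline [segmentation_config()].
#' @param lumen_values,dfa_values_mm2_s grids of settings; default a
#'   +/- 10% sweep around the baseline.
#' @param roi optional logical mask.
#' @return Data frame with one row per setting: thresholds and mean
#'   `f_E`, `f_S`, `f_L`, `f_U` over the (ROI) volume.
#' @export
threshold_sensitivity <- function(gre, tensor, medium,
                                  config = segmentation_config(),
                                  lumen_values = config$lumen_threshold_value *
                                    c(0.9, 1, 1.1),
                                  dfa_values_mm2_s = config$dfa_threshold_mm2_s *
                                    c(0.9, 1, 1.1),
                                  roi = NULL) {
  grid <- expand.grid(lumen_threshold_value = lumen_values,
                      dfa_threshold_mm2_s = dfa_values_mm2_s)
  L <- esl_labels()
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$lumen_threshold_value <- grid$lumen_threshold_value[i]
    cfg$dfa_threshold_mm2_s <- grid$dfa_threshold_mm2_s[i]
    la <- segment_lumen_air(gre, medium, cfg)
    st <- segment_stroma(tensor, cfg, exclude = la$lumen | la$air)
    labels <- compose_esl(la$lumen, st, la$air, roi)
    n <- if (is.null(roi)) length(labels) else sum(roi)
    sel <- if (is.null(roi)) labels else labels[roi]
    data.frame(grid[i, ],
               f_E = sum(sel == L["epithelium"]) / n,
               f_S = sum(sel == L["stroma"]) / n,
               f_L = sum(sel == L["lumen"]) / n,
               f_U = sum(sel == L["air"]) / n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
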