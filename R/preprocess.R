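# Preprocessing for the multidimensional dMRI and DTI image stacks:
# Marchenko-Pastur PCA denoising, direction averaging, block downsampling,
# b = 0 normalisation and the cylindrical analysis ROI.

# Coerce a list of equally shaped 3D arrays to a 4D array.
.as_stack <- function(stack) {
  if (is.list(stack)) {
    d <- dim(stack[[1]])
    arr <- array(unlist(stack, use.names = FALSE), c(d, length(stack)))
    return(arr)
  }
  stopifnot(length(dim(stack)) == 4)
  stack
}

#' Marchenko-Pastur PCA denoising of an image stack
#'
#' Sliding-patch PCA with centre-voxel write-back: for each voxel, the
#' patch-by-volume data matrix is eigen-decomposed and eigenvalues
#' compatible with the Marchenko-Pastur law of pure noise are suppressed.
#' The noise level is estimated per patch as the mean of the discarded
#' eigenvalues, accepting the largest noise set whose eigenvalue range
#' matches the MP support width (Veraart-style classification). Patches are
#' clipped at the volume borders so the output shape equals the input.
#'
#' @param stack list of co-registered 3D arrays, or a 4D array, with the
#'   image series along the last dimension (>= 2 volumes).
#' @param patch_edge odd patch edge length in voxels (default 5).
#' @return List with `denoised` (4D array), `sigma` (3D array of per-voxel
#'   noise SD estimates) and `n_components` (3D array of retained signal
#'   components).
#' @export
mppca_denoise <- function(stack, patch_edge = 5) {
  arr <- .as_stack(stack)
  d <- dim(arr)
  nvol <- d[4]
  if (nvol < 2) stop("need at least 2 volumes to denoise")
  if (patch_edge %% 2 != 1) stop("patch_edge must be odd")
  if (any(patch_edge > d[1:3]))
    stop("patch larger than volume: reduce patch_edge")
  hw <- (patch_edge - 1) %/% 2
  X <- matrix(arr, prod(d[1:3]), nvol)
  out <- matrix(0, prod(d[1:3]), nvol)
  sig <- array(NA_real_, d[1:3])
  ncomp <- array(NA_integer_, d[1:3])
  # Precompute clipped window index vectors per axis position.
  win <- function(i, n) {
    lo <- max(1, min(i - hw, n - patch_edge + 1))
    lo:(lo + patch_edge - 1)
  }
  wins <- lapply(1:3, function(ax)
    lapply(seq_len(d[ax]), function(i) win(i, d[ax])))
  nx <- d[1]; nxy <- d[1] * d[2]
  # patch index offsets relative to the centre voxel (interior case)
  rel <- -hw:hw
  off0 <- as.vector(outer(outer(rel, rel * nx, "+"), rel * nxy, "+"))
  row0 <- match(0, off0)
  for (k in seq_len(d[3])) {
    wk <- wins[[3]][[k]]
    int_k <- k > hw && k <= d[3] - hw
    for (j in seq_len(d[2])) {
      wj <- wins[[2]][[j]]
      int_jk <- int_k && j > hw && j <= d[2] - hw
      off <- outer((wj - 1) * nx, (wk - 1) * nxy, "+")
      for (i in seq_len(d[1])) {
        interior <- int_jk && i > hw && i <= d[1] - hw
        idx <- if (interior) (i + (j - 1) * nx + (k - 1) * nxy) + off0 else
          as.vector(outer(wins[[1]][[i]], off, "+"))
        P <- X[idx, , drop = FALSE]
        M <- nrow(P)
        e <- eigen(crossprod(P) / M, symmetric = TRUE)
        vals <- pmax(e$values, 0)            # descending
        Rrank <- nvol
        p_sel <- 0L
        sig2 <- 0
        for (p in 0:(Rrank - 1)) {
          nv <- vals[(p + 1):Rrank]
          s1 <- mean(nv)
          gam <- (Rrank - p) / M
          s2 <- (nv[1] - nv[length(nv)]) / (4 * sqrt(gam))
          if (s2 <= s1) { p_sel <- p; sig2 <- s1; break }
          p_sel <- p + 1L
          sig2 <- 0
        }
        centre <- i + (j - 1) * nx + (k - 1) * nxy
        row <- if (interior) row0 else match(centre, idx)
        if (p_sel == 0L) {
          out[centre, ] <- 0       # all variance classified as noise
        } else if (p_sel >= Rrank) {
          out[centre, ] <- P[row, ]
        } else {
          V <- e$vectors[, seq_len(p_sel), drop = FALSE]
          out[centre, ] <- (P[row, , drop = FALSE] %*% V) %*% t(V)
        }
        sig[i, j, k] <- sqrt(max(sig2, 0))
        ncomp[i, j, k] <- p_sel
      }
    }
  }
  list(denoised = array(out, d), sigma = sig, n_components = ncomp)
}

#' Average diffusion-encoding directions
#'
#' Voxelwise arithmetic mean over direction volumes; averaging n i.i.d.
#' noisy directions improves SNR by sqrt(n) (~2.5 for six directions).
#'
#' @param dwis list of direction volumes (equal shapes) or a 4D array.
#' @param n_directions expected number of volumes (checked when given).
#' @return A single 3D array.
#' @export
direction_average <- function(dwis, n_directions = NULL) {
  arr <- .as_stack(dwis)
  if (!is.null(n_directions) && dim(arr)[4] != n_directions)
    stop("expected ", n_directions, " direction volumes, got ", dim(arr)[4])
  d <- dim(arr)
  out <- rowMeans(matrix(arr, prod(d[1:3]), d[4]))
  array(out, d[1:3])
}

#' Downsample a volume by block averaging
#'
#' Mean over non-overlapping blocks of `factors` voxels per axis; the SNR
#' gain is sqrt(prod(factors)) (~4.2 for 3 x 3 x 2). The shape must be
#' divisible by the factors -- no implicit cropping.
#'
#' @param volume 3D array; a `voxel_um` attribute, if present, is
#'   multiplied by the factors.
#' @param factors integer length-3 vector of per-axis block sizes.
#' @return The block-averaged array.
#' @export
block_downsample <- function(volume, factors) {
  d <- dim(volume)
  factors <- as.integer(factors)
  if (any(d %% factors != 0))
    stop("volume shape (", paste(d, collapse = "x"),
         ") not divisible by factors (", paste(factors, collapse = "x"), ")")
  out <- .block_mean(volume, factors)
  vu <- attr(volume, "voxel_um")
  if (!is.null(vu)) attr(out, "voxel_um") <- rep_len(vu, 3) * factors
  out
}

#' Normalise a diffusion-weighted volume by the b = 0 volume
#'
#' Voxelwise ratio accounting for T2 heterogeneity. Voxels whose b = 0
#' intensity falls below `floor` are set to `NA` and flagged in the `valid`
#' attribute rather than raising an error.
#'
#' @param dwi,b0 3D arrays of equal shape.
#' @param floor minimum usable b = 0 intensity; default 10% of the median
#'   positive b = 0 value.
#' @return Array of normalised signals with logical attribute `valid`.
#' @export
normalize_by_b0 <- function(dwi, b0, floor = NULL) {
  stopifnot(all(dim(dwi) == dim(b0)))
  if (is.null(floor)) {
    pos <- b0[b0 > 0]
    floor <- if (length(pos)) 0.1 * stats::median(pos) else 0
  }
  valid <- is.finite(b0) & b0 >= floor & b0 > 0
  out <- dwi / b0
  out[!valid] <- NA_real_
  attr(out, "valid") <- valid
  attr(out, "floor") <- floor
  out
}

#' Cylindrical analysis region of interest
#'
#' Mask of voxels whose full in-plane extent lies inside a cylinder aligned
#' with a grid axis (the analysis keeps only voxels fully contained in the
#' region enclosing the samples).
#'
#' @param dim_vox grid dimensions (length 3).
#' @param voxel_um per-axis voxel edges (scalar or length 3), um.
#' @param radius_um cylinder radius, um (> 0).
#' @param center_um in-plane cylinder centre relative to the grid centre
#'   (length 2, um).
#' @param axis cylinder axis: 1, 2 or 3 (default 3, the tube axis).
#' @return Logical 3D array; attribute `n_voxels` counts included voxels.
#'   An empty mask triggers a warning.
#' @export
cylinder_roi <- function(dim_vox, voxel_um, radius_um,
                         center_um = c(0, 0), axis = 3) {
  stopifnot(radius_um > 0, axis %in% 1:3)
  voxel_um <- rep_len(voxel_um, 3)
  plane <- setdiff(1:3, axis)
  c1 <- .centre_coords(dim_vox[plane[1]], voxel_um[plane[1]]) - center_um[1]
  c2 <- .centre_coords(dim_vox[plane[2]], voxel_um[plane[2]]) - center_um[2]
  # farthest corner of the voxel footprint from the cylinder axis
  m1 <- abs(c1) + voxel_um[plane[1]] / 2
  m2 <- abs(c2) + voxel_um[plane[2]] / 2
  inside2d <- outer(m1^2, m2^2, "+") <= radius_um^2
  mask <- array(FALSE, dim_vox)
  perm <- order(c(plane, axis))
  full <- aperm(array(inside2d, c(length(c1), length(c2), dim_vox[axis])),
                perm)
  mask[] <- full
  if (!any(mask)) warning("cylinder ROI contains no voxels")
  attr(mask, "n_voxels") <- sum(mask)
  mask
}
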