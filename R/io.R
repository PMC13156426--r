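# NIfTI volume I/O and small serialisation helpers.

#' Read or write a NIfTI volume
#'
#' NIfTI-1 round trip preserving data values and the voxel-size header.
#' Voxel sizes are carried on the R side as a `voxel_um` attribute (um) and
#' stored in the NIfTI header in mm.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param volume numeric array (3D or 4D).
#' @param voxel_um voxel edge length(s) in um (scalar or per-axis); taken
#'   from the array's `voxel_um` attribute when omitted.
#' @return `read_volume()` returns the array with a `voxel_um` attribute;
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  .check_nifti_path(path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  vol <- as.array(img)
  pd <- RNifti::pixdim(img)
  attributes(vol) <- list(dim = dim(vol))
  attr(vol, "voxel_um") <- pd[seq_len(min(3, length(pd)))] * 1000
  vol
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, voxel_um = attr(volume, "voxel_um")) {
  .check_nifti_path(path)
  if (is.null(voxel_um)) voxel_um <- 1000
  voxel_mm <- rep_len(voxel_um, 3) / 1000
  arr <- volume
  attributes(arr) <- list(dim = dim(volume))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

.check_nifti_path <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported volume format (expected .nii or .nii.gz): ", path)
  invisible(path)
}

# Small stable hash (FNV-1a, 32-bit) of an R object's serialisation; used
# to stamp outputs with the generating configuration.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
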