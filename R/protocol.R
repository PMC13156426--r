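# Acquisition protocol and unit conversions.
#
# Internal unit system throughout the package: b in ms/um^2 (1000 s/mm^2 ==
# 1.0 ms/um^2), times in ms, lengths in um, diffusivities in um^2/ms. This
# keeps all fitted quantities near unit magnitude; converters to/from the
# conventional s/mm^2 and mm^2/s scales live at the I/O boundary.

#' Convert b-values between s/mm^2 and the internal ms/um^2 scale
#'
#' @param b_si b-value(s) in s/mm^2.
#' @param b b-value(s) in ms/um^2.
#' @return Converted numeric vector.
#' @examples
#' b_to_internal(1000)  # 1.0 ms/um^2
#' @export
b_to_internal <- function(b_si) b_si / 1000

#' @rdname b_to_internal
#' @export
b_to_si <- function(b) b * 1000

#' Convert a diffusivity-type quantity from mm^2/s to um^2/ms
#'
#' 1 mm^2/s = 1000 um^2/ms, so e.g. the stroma segmentation cutoff
#' 1.4e-4 mm^2/s becomes 0.14 um^2/ms.
#'
#' @param x quantity in mm^2/s.
#' @return quantity in um^2/ms.
#' @export
diffusivity_to_internal <- function(x) x * 1000

#' Canonical multidimensional dMRI protocol
#'
#' The 10 stimulated-echo (STEAM) diffusion-weighted sequences used for the
#' multidimensional acquisition: five b-values (1.0-2.0 ms/um^2), each with a
#' short and a long diffusion time, all with gradient duration delta = 2 ms
#' and 6 encoding directions, plus the spin-echo b = 0 sequence used for
#' normalisation.
#'
#' @return A data frame of class `esl_protocol` with columns `id`, `b`
#'   (ms/um^2), `delta` (ms), `Delta` (ms), `n_directions` and `kind`
#'   (one of `"steam_dwi"`, `"se_b0"`).
#' @examples
#' canonical_protocol()
#' @export
canonical_protocol <- function() {
  b <- rep(c(1.0, 1.25, 1.5, 1.75, 2.0), each = 2)
  Delta <- c(15, 40, 20, 60, 30, 80, 40, 100, 50, 120)
  prot <- data.frame(
    id = c(sprintf("b%d_D%d", round(b * 1000), Delta), "se_b0"),
    b = c(b, 0),
    delta = c(rep(2, 10), NA_real_),
    Delta = c(Delta, NA_real_),
    n_directions = c(rep(6L, 10), 1L),
    kind = c(rep("steam_dwi", 10), "se_b0"),
    stringsAsFactors = FALSE
  )
  class(prot) <- c("esl_protocol", "data.frame")
  prot
}

#' STEAM diffusion-weighted subset of a protocol
#'
#' @param protocol an `esl_protocol` data frame; defaults to
#'   [canonical_protocol()].
#' @return The rows with `kind == "steam_dwi"`.
#' @export
steam_sequences <- function(protocol = canonical_protocol()) {
  protocol[protocol$kind == "steam_dwi", , drop = FALSE]
}

#' DTI acquisition parameters of the microscopy protocol
#'
#' Spin-echo DTI at 40 um isotropic: two b = 0 volumes and six volumes at
#' b = 1.2 ms/um^2 (1200 s/mm^2) with delta/Delta = 2/12 ms, sharing the six
#' gradient directions of the STEAM protocol.
#'
#' @return A list with elements `b` (ms/um^2), `delta`, `Delta` (ms),
#'   `n_b0` and `directions` (6 x 3 unit row vectors).
#' @export
dti_protocol <- function() {
  list(b = 1.2, delta = 2, Delta = 12, n_b0 = 2L,
       directions = encoding_directions())
}

#' Six diffusion encoding directions
#'
#' The electrostatic-repulsion-optimal 6-direction set (icosahedron
#' vertices), shared by the DTI and STEAM sequences.
#'
#' @return A 6 x 3 matrix of unit row vectors.
#' @export
encoding_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  d <- rbind(
    c(0,  1,  phi), c(0, -1,  phi),
    c(1,  phi, 0),  c(-1, phi, 0),
    c(phi, 0,  1),  c(phi, 0, -1)
  )
  d / sqrt(rowSums(d^2))
}

#' Gradient factor gamma*g from a b-value and pulse timings
#'
#' Uses the pulsed-gradient relation b = (gamma g delta)^2 (Delta - delta/3)
#' to recover the gamma*g product needed by the restricted-diffusion sphere
#' signal. The stimulated-echo pair is treated as a pulsed-gradient pair with
#' the stated (delta, Delta).
#'
#' @param b b-value in ms/um^2.
#' @param delta gradient pulse duration in ms (> 0).
#' @param Delta gradient pulse separation in ms (> delta/3).
#' @return gamma*g in um^-1 ms^-1 (vectorised over `b`).
#' @seealso [b_from_gamma_g()] for the inverse.
#' @examples
#' gamma_g_from_b(1.0, 2, 15)
#' @export
gamma_g_from_b <- function(b, delta, Delta) {
  if (any(delta <= 0) || any(Delta <= delta / 3))
    stop("invalid timing: need delta > 0 and Delta > delta/3")
  if (any(b < 0)) stop("b must be non-negative")
  sqrt(b / (delta^2 * (Delta - delta / 3)))
}

#' @rdname gamma_g_from_b
#' @param gamma_g gamma*g product in um^-1 ms^-1.
#' @export
b_from_gamma_g <- function(gamma_g, delta, Delta) {
  if (any(delta <= 0) || any(Delta <= delta / 3))
    stop("invalid timing: need delta > 0 and Delta > delta/3")
  gamma_g^2 * delta^2 * (Delta - delta / 3)
}

#' Read or write a protocol table
#'
#' Serialised with b on the conventional s/mm^2 scale (column `b_s_per_mm2`);
#' conversion to the internal ms/um^2 scale happens on read. CSV and YAML
#' formats are supported, chosen by file extension.
#'
#' @param path file path ending in `.csv`, `.yaml` or `.yml`.
#' @param protocol an `esl_protocol` data frame.
#' @return `read_protocol()` returns an `esl_protocol` data frame;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    yaml = ,
    yml = do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame)),
    stop("unsupported protocol format: .", ext)
  )
  prot <- data.frame(
    id = as.character(tab$id),
    b = b_to_internal(as.numeric(tab$b_s_per_mm2)),
    delta = as.numeric(tab$delta_ms),
    Delta = as.numeric(tab$Delta_ms),
    n_directions = as.integer(tab$n_directions),
    kind = as.character(tab$kind),
    stringsAsFactors = FALSE
  )
  dw <- prot$kind %in% c("steam_dwi", "dti_dwi")
  if (any(dw & (is.na(prot$delta) | prot$delta <= 0)))
    stop("diffusion-weighted sequences need delta > 0")
  if (any(dw & prot$Delta <= prot$delta, na.rm = TRUE))
    stop("need Delta > delta")
  class(prot) <- c("esl_protocol", "data.frame")
  prot
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  out <- data.frame(
    id = protocol$id,
    b_s_per_mm2 = b_to_si(protocol$b),
    delta_ms = protocol$delta,
    Delta_ms = protocol$Delta,
    n_directions = protocol$n_directions,
    kind = protocol$kind
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lapply(seq_len(nrow(out)), function(i) as.list(out[i, ])),
                     path)
  } else {
    stop("unsupported protocol format: .", ext)
  }
  invisible(path)
}
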