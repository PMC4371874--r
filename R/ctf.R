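#' Contrast transfer function parameters
#'
#' Underfocus is positive.  The default voltage is 300 kV; the electron
#' wavelength is derived relativistically (0.0197 A at 300 kV).
#'
#' @param defocus_um underfocus in micrometres (> 0 for simulated data).
#' @param cs_mm spherical aberration in mm.
#' @param kv accelerating voltage in kV.
#' @param amp_contrast amplitude contrast fraction in `[0, 1]`.
#' @param apix_ang sampling in Angstrom per pixel.
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_um = 3.2, cs_mm = 2.0, kv = 300,
                       amp_contrast = 0.07, apix_ang = 2.3) {
  stopifnot(defocus_um > 0, apix_ang > 0, kv > 0,
            amp_contrast >= 0, amp_contrast <= 1)
  structure(list(defocus_um = defocus_um, cs_mm = cs_mm, kv = kv,
                 amp_contrast = amp_contrast, apix_ang = apix_ang),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(
    "<ctf_params> defocus %.3g um, Cs %.3g mm, %g kV, A %.3g, %.3g A/px\n",
    x$defocus_um, x$cs_mm, x$kv, x$amp_contrast, x$apix_ang))
  invisible(x)
}

#' Relativistic electron wavelength
#' @param kv accelerating voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(kv) {
  v <- kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the contrast transfer function
#'
#' `CTF(f) = -[sqrt(1 - A^2) sin(gamma) + A cos(gamma)]` with
#' `gamma(f) = pi * lambda * dz * f^2 - (pi/2) * Cs * lambda^3 * f^4`,
#' underfocus positive; `CTF(0) = -A`.
#'
#' @param params a [ctf_params()].
#' @param freq spatial frequency (1/Angstrom), any shape.
#' @return real transfer function values, same shape as `freq`.
#' @export
ctf_evaluate <- function(params, freq) {
  stopifnot(inherits(params, "ctf_params"))
  lam <- electron_wavelength(params$kv)
  dz <- params$defocus_um * 1e4        # um -> A
  cs <- params$cs_mm * 1e7             # mm -> A
  g <- pi * lam * dz * freq^2 - (pi / 2) * cs * lam^3 * freq^4
  a <- params$amp_contrast
  -(sqrt(1 - a^2) * sin(g) + a * cos(g))
}

# |f| grid in natural fft order for an n x n image
ctf_freq_grid <- function(n, apix) {
  f <- freq_axis_fft(n, apix)
  sqrt(outer(f^2, f^2, `+`))
}

#' Apply a CTF to an image
#'
#' Multiplies the image Fourier transform by the transfer function
#' (`mode = "multiply"`, as used both to simulate image formation and to
#' correct phases, since multiplying twice leaves all-positive CTF^2
#' weights) or by its sign (`mode = "phase_flip"`).  Both keep the output
#' real because the transfer function is real and centrosymmetric.
#'
#' @param image an [image_grid()] (square, real).
#' @param params a [ctf_params()]; its `apix_ang` is overridden by the
#'   image sampling when they disagree.
#' @param mode `"multiply"` or `"phase_flip"`.
#' @return filtered [image_grid()].
#' @export
apply_ctf <- function(image, params, mode = c("multiply", "phase_flip")) {
  mode <- match.arg(mode)
  n <- nrow(image)
  stopifnot(n == ncol(image))
  apx <- attr(image, "apix")
  if (is.null(apx)) apx <- params$apix_ang
  h <- ctf_evaluate(params, ctf_freq_grid(n, apx))
  if (mode == "phase_flip") h <- sign(h)
  ft <- fft(as_plain_array(image)) * h
  image_grid(Re(fft(ft, inverse = TRUE)) / n^2, apx)
}

#' Apply per-segment CTFs to a whole stack
#'
#' Convenience wrapper over [apply_ctf()]: multiplies (or phase-flips)
#' each segment by its own CTF, as done to correct phases before
#' refinement.
#'
#' @param stack 3-D segment stack with an `apix` attribute.
#' @param ctf_table data.frame with per-segment `defocus_um`, `cs_mm`,
#'   `kv`, `amp_contrast` (e.g. a simulation truth table).
#' @param mode passed to [apply_ctf()].
#' @return corrected stack of the same shape.
#' @export
apply_ctf_stack <- function(stack, ctf_table,
                            mode = c("multiply", "phase_flip")) {
  mode <- match.arg(mode)
  apx <- attr(stack, "apix")
  m <- dim(stack)[3]
  stopifnot(nrow(ctf_table) == m)
  out <- stack
  for (i in seq_len(m)) {
    p <- ctf_params(ctf_table$defocus_um[i], ctf_table$cs_mm[i],
                    ctf_table$kv[i], ctf_table$amp_contrast[i], apx)
    out[, , i] <- apply_ctf(image_grid(stack[, , i], apx), p, mode)
  }
  out
}

#' Sum of squared CTFs on a radial frequency grid
#'
#' Helper for amplitude correction of reconstructions whose input images
#' were multiplied by their CTFs: evaluates `sum_i CTF_i(f)^2` for a list
#' of defocus values.
#'
#' @param ctfs list of [ctf_params()].
#' @param freq frequency array (1/Angstrom).
#' @return array of `sum CTF^2`, same shape as `freq`.
#' @export
sum_ctf_squared <- function(ctfs, freq) {
  out <- array(0, dim = if (is.null(dim(freq))) length(freq) else dim(freq))
  for (p in ctfs) out <- out + ctf_evaluate(p, freq)^2
  out
}

#' Apply an average CTF-squared amplitude weighting to a volume
#'
#' Reference projections are compared against segments whose Fourier
#' amplitudes carry a CTF^2 weighting (multiplied once by the microscope
#' and once more during phase correction).  Weighting a clean reference
#' volume by the dataset-average CTF^2 makes the comparison spectrally
#' matched.
#'
#' @param vol a [volume_grid()].
#' @param ctfs list of [ctf_params()] spanning the dataset.
#' @return filtered [volume_grid()].
#' @export
ctf_weight_volume <- function(vol, ctfs) {
  n <- dim(vol)[1]
  apx <- apix(vol)
  f <- vol_freq_grid(n, apx)
  w <- sum_ctf_squared(ctfs, f) / length(ctfs)
  out <- Re(fft(fft(as_plain_array(vol)) * w, inverse = TRUE)) / n^3
  volume_grid(array(out, rep(n, 3)), apx)
}
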