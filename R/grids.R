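#' Real-space density grids
#'
#' A `volume_grid` is a cubic 3-D density array, a `image_grid` a square 2-D
#' density array; both carry the sampling `apix` (Angstrom per voxel/pixel)
#' as an attribute.  The helix axis of filament volumes runs along the third
#' (z) array index; images are indexed `[u, v]` with the filament axis along
#' `v` at zero tilt and zero in-plane rotation.  The object (and Fourier)
#' center sits at 0-based index `floor(n/2)`, matching the `fftshift`
#' convention.
#'
#' @param data numeric array (3-D cubic for volumes, 2-D square for images).
#' @param apix sampling in Angstrom per voxel/pixel (> 0).
#' @return The array with class `volume_grid` / `image_grid` and attribute
#'   `apix`.
#' @export
volume_grid <- function(data, apix) {
  d <- dim(data)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("volume_grid requires a cubic 3-D array")
  if (!is.numeric(apix) || apix <= 0) stop("apix must be > 0")
  structure(data, apix = apix, class = "volume_grid")
}

#' @rdname volume_grid
#' @export
image_grid <- function(data, apix) {
  d <- dim(data)
  if (length(d) != 2L || d[1] != d[2])
    stop("image_grid requires a square matrix")
  if (!is.numeric(apix) || apix <= 0) stop("apix must be > 0")
  structure(data, apix = apix, class = "image_grid")
}

#' Sampling of a grid in Angstrom per pixel
#' @param x a grid, spectrum or stack carrying an `apix` attribute.
#' @return numeric scalar.
#' @export
apix <- function(x) {
  a <- attr(x, "apix")
  if (is.null(a)) stop("object carries no apix attribute")
  a
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d^3 voxels, %.4g A/vox (%.4g A box)\n",
              dim(x)[1], apix(x), dim(x)[1] * apix(x)))
  invisible(x)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d^2 pixels, %.4g A/px\n", dim(x)[1], apix(x)))
  invisible(x)
}

# strip grid classes but keep data/dim (internal)
as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Centered frequency axis
#'
#' Frequencies (1/Angstrom) for an `n`-point axis sampled at `apix`, in
#' fftshifted (origin-centered) order: `k/(n*apix)` for
#' `k = -floor(n/2) .. ceiling(n/2)-1`.
#' @param n axis length.
#' @param apix sampling in Angstrom.
#' @return numeric vector of length `n`.
#' @export
freq_axis <- function(n, apix) {
  (seq_len(n) - 1 - floor(n / 2)) / (n * apix)
}

# frequency axis in natural fft (DC-first) order
freq_axis_fft <- function(n, apix) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / (n * apix)
}

#' Shift the zero-frequency component to the array center (and back)
#'
#' `fftshift` moves the DC term from index 1 to index `floor(n/2)+1` along
#' every dimension; `ifftshift` is its inverse (they coincide for even
#' sizes).
#' @param x numeric or complex array.
#' @return array of the same shape.
#' @export
fftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + ceiling(n / 2)) %% n) + 1)
  y <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  a <- attributes(x); a$dim <- dim(y); attributes(y) <- a
  y
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1)
  y <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  a <- attributes(x); a$dim <- dim(y); attributes(y) <- a
  y
}

#' Nyquist frequency and practical resolution bounds
#'
#' `nyquist_freq` is `1/(2*apix)`; `resolution_bound` converts a fraction of
#' Nyquist into a real-space resolution in Angstrom.  At 2.3 A/px the
#' conventional two-thirds-of-Nyquist bound evaluates to about 7 A.
#'
#' @param apix sampling in Angstrom per pixel.
#' @param fraction fraction of the Nyquist frequency deemed usable.
#' @return frequency in 1/Angstrom, or resolution in Angstrom.
#' @export
nyquist_freq <- function(apix) 1 / (2 * apix)

#' @rdname nyquist_freq
#' @export
resolution_bound <- function(apix, fraction = 2 / 3) {
  1 / (fraction * nyquist_freq(apix))
}
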