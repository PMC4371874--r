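#' Power spectrum of an image
#'
#' `|FT|^2` with the origin shifted to the box center.  The axes are
#' (radial frequency R along the first index, axial frequency Z along the
#' second) in 1/Angstrom; spectra of real images obey Friedel symmetry.
#' `log_scale` stores `log1p(intensity)` for display; analysis operations
#' require linear intensities.
#'
#' @param image an [image_grid()] (square, real).
#' @param log_scale logical, display scaling.
#' @return object of class `power_spectrum`: matrix with attributes `apix`
#'   and `log_scaled`.
#' @export
power_spectrum <- function(image, log_scale = FALSE) {
  n <- nrow(image)
  stopifnot(n == ncol(image))
  p <- fftshift(Mod(fft(as_plain_array(image)))^2)
  if (log_scale) p <- log1p(p)
  structure(p, apix = apix(image), log_scaled = log_scale,
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d^2, %.4g A/px%s\n", nrow(x), apix(x),
              if (attr(x, "log_scaled")) ", log-scaled" else ""))
  invisible(x)
}

#' Average power spectrum of a segment set
#'
#' Mean of the per-segment power spectra, optionally after rotating each
#' segment in plane by minus its assigned psi so the filament axis is
#' vertical.
#'
#' @param segments 3-D stack (n x n x m) or list of [image_grid()]s.
#' @param psi_deg assigned in-plane rotations (recycled; used when
#'   `align_axis` is TRUE).
#' @param align_axis rotate by `-psi` before the transform.
#' @param apix_ang sampling override when the stack carries none.
#' @return a `power_spectrum` (linear intensities).
#' @export
average_power_spectrum <- function(segments, psi_deg = 0,
                                   align_axis = TRUE, apix_ang = NULL) {
  if (is.list(segments)) {
    apx <- apix(segments[[1]])
    m <- length(segments)
    get <- function(i) as_plain_array(segments[[i]])
    n <- nrow(segments[[1]])
  } else {
    if (is.null(apix_ang)) apix_ang <- apix(segments)
    apx <- apix_ang
    m <- dim(segments)[3]
    get <- function(i) segments[, , i]
    n <- dim(segments)[1]
  }
  if (m < 1L) stop("no segments to average")
  psi_deg <- rep_len(psi_deg, m)
  acc <- matrix(0, n, n)
  for (i in seq_len(m)) {
    img <- get(i)
    if (align_axis && psi_deg[i] != 0)
      img <- cpp_rotate2d(img, -psi_deg[i] * pi / 180)
    acc <- acc + Mod(fft(img))^2
  }
  structure(fftshift(acc / m), apix = apx, log_scaled = FALSE,
            class = "power_spectrum")
}

#' Central section of a 3-D power spectrum
#'
#' By the projection-slice theorem the power spectrum of a projection
#' equals the central section of the 3-D power spectrum at the same
#' orientation; this samples that plane directly by trilinear
#' interpolation.
#'
#' @param vol a cubic [volume_grid()].
#' @param azimuth_deg,tilt_deg section orientation (degrees).
#' @param oversample zero-padding factor refining the Fourier sampling
#'   before interpolation (2 keeps the interpolation error well below the
#'   spectral features).
#' @return a `power_spectrum` (same grid/apix as a projection's spectrum).
#' @export
central_section <- function(vol, azimuth_deg = 0, tilt_deg = 0,
                            oversample = 2L) {
  n <- dim(vol)[1]
  np <- n * oversample
  pad <- array(0, rep(np, 3))
  lo <- floor(np / 2) - floor(n / 2)
  idx <- (lo + 1):(lo + n)
  pad[idx, idx, idx] <- as_plain_array(vol)
  ps3 <- fftshift(Mod(fft(pad))^2)
  b <- orientation_basis(azimuth_deg, tilt_deg, 0)
  # sample every `oversample`-th padded Fourier voxel onto the n x n grid
  sec <- cpp_central_plane(as.numeric(ps3), np,
                           b$u * oversample, b$v * oversample)
  cen_p <- floor(np / 2) + 1L
  cen <- floor(n / 2) + 1L
  keep <- (cen_p - cen + 1L):(cen_p - cen + n)
  sec <- sec[keep, keep]
  # scale to match |FT_2D(projection)|^2 = apix^2 |FT_3D slice|^2
  structure(sec * apix(vol)^2, apix = apix(vol), log_scaled = FALSE,
            class = "power_spectrum")
}

#' Radial intensity profile of a layer line
#'
#' Integrates spectrum rows within `half_width_px` Fourier pixels of the
#' axial frequency `z_freq`, averages the two Friedel mates, and folds the
#' horizontal axis about the meridian.
#'
#' @param spec a linear-intensity `power_spectrum`.
#' @param z_freq axial frequency of the line, 1/Angstrom (0 < z < Nyquist).
#' @param half_width_px band half-width in Fourier pixels.
#' @return data.frame `R_freq` (1/Angstrom, >= 0), `intensity`; the Fourier
#'   pixel width is attached as attribute `fourier_px`.
#' @export
layer_line_profile <- function(spec, z_freq, half_width_px = 1L) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (isTRUE(attr(spec, "log_scaled")))
    stop("layer_line_profile needs linear intensities")
  n <- nrow(spec)
  apx <- apix(spec)
  if (z_freq <= 0 || z_freq >= nyquist_freq(apx))
    stop("z_freq outside (0, Nyquist)")
  cen <- floor(n / 2) + 1L
  jz <- z_freq * n * apx                     # rows above center
  rows_p <- round(cen + jz) + seq.int(-half_width_px, half_width_px)
  rows_m <- round(cen - jz) + seq.int(-half_width_px, half_width_px)
  rows_p <- rows_p[rows_p >= 1 & rows_p <= n]
  rows_m <- rows_m[rows_m >= 1 & rows_m <= n]
  band <- (colSums(t(spec[, rows_p, drop = FALSE])) +
             colSums(t(spec[, rows_m, drop = FALSE]))) / 2
  # fold u about the meridian (Friedel mates across the origin)
  kmax <- n - cen
  prof <- vapply(0:kmax, function(k) {
    v <- band[cen + k]
    if (cen - k >= 1 && k > 0) v <- (v + band[cen - k]) / 2
    v
  }, numeric(1))
  out <- data.frame(R_freq = (0:kmax) / (n * apx), intensity = prof)
  attr(out, "fourier_px") <- 1 / (n * apx)
  out
}

#' Classify a layer-line profile as meridional or off-meridional
#'
#' The profile's global maximum above the noise floor decides: a peak more
#' than one Fourier pixel off the meridian is `off_meridian`, otherwise
#' `on_meridian`; if nothing exceeds the floor the result is
#' `indeterminate`.  The default floor is `median + 3 * MAD` of the outer
#' third of the profile.
#'
#' @param profile output of [layer_line_profile()].
#' @param noise_floor numeric floor, or NULL for the default rule.
#' @return list with `class` (`"on_meridian"`, `"off_meridian"` or
#'   `"indeterminate"`), `peak_R` (1/Angstrom, NA when indeterminate) and
#'   `noise_floor`.
#' @export
meridional_classification <- function(profile, noise_floor = NULL) {
  stopifnot(nrow(profile) >= 5L)
  fpx <- attr(profile, "fourier_px")
  if (is.null(fpx)) fpx <- diff(profile$R_freq[1:2])
  if (is.null(noise_floor)) {
    outer3 <- profile$intensity[profile$R_freq >
                                  max(profile$R_freq) * 2 / 3]
    noise_floor <- median(outer3) + 3 * mad(outer3)
  }
  above <- profile$intensity > noise_floor
  if (!any(above))
    return(list(class = "indeterminate", peak_R = NA_real_,
                noise_floor = noise_floor))
  i <- which.max(profile$intensity)
  peak_R <- profile$R_freq[i]
  list(class = if (peak_R > fpx * (1 + 1e-9)) "off_meridian"
       else "on_meridian",
       peak_R = peak_R, noise_floor = noise_floor)
}

#' Export a spectrum for display
#'
#' Writes a log-scaled PNG (display only) or the spectrum as an MRC image.
#' @param spec a `power_spectrum`.
#' @param path output file; extension picks the format (.png or .mrc).
#' @return the path, invisibly.
#' @export
export_spectrum <- function(spec, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = nrow(spec), height = ncol(spec))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    x <- if (attr(spec, "log_scaled")) spec else log1p(spec)
    graphics::image(unclass(x), axes = FALSE, useRaster = TRUE,
                    col = grDevices::gray.colors(256))
  } else {
    write_mrc(image_grid(unclass(spec), apix(spec)), path)
  }
  invisible(path)
}
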