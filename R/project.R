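#' Orientation basis for projections
#'
#' Intrinsic z-y-z convention: `azimuth` spins the filament about its own
#' (z) axis, `tilt` rocks the axis out of the projection plane, `psi`
#' rotates in the image plane.  Returns the unit vectors (in volume
#' coordinates) of the image horizontal axis `u`, image vertical axis `v`
#' (the filament axis at zero tilt/psi) and the viewing/ray direction `d`.
#'
#' @param azimuth_deg,tilt_deg,psi_deg angles in degrees.
#' @return list with numeric length-3 vectors `u`, `v`, `d`.
#' @export
orientation_basis <- function(azimuth_deg = 0, tilt_deg = 0, psi_deg = 0) {
  az <- azimuth_deg * pi / 180
  tl <- tilt_deg * pi / 180
  ps <- psi_deg * pi / 180
  d <- c(cos(tl) * cos(az), cos(tl) * sin(az), sin(tl))
  v <- c(-sin(tl) * cos(az), -sin(tl) * sin(az), cos(tl))
  u <- c(-sin(az), cos(az), 0)
  list(u = cos(ps) * u + sin(ps) * v,
       v = -sin(ps) * u + cos(ps) * v,
       d = d)
}

#' Project a volume to an image
#'
#' Line-integral projection of a cubic volume after orienting it by
#' (azimuth, out-of-plane tilt, in-plane psi) and shifting the image by
#' `shift_px` pixels.  The integral carries the voxel step, so the image
#' sum equals the volume sum times `apix` (up to density leaving the box).
#'
#' @param vol a [volume_grid()].
#' @param azimuth_deg,tilt_deg,psi_deg orientation in degrees (see
#'   [orientation_basis()]).
#' @param shift_px length-2 image shift (u, v) in pixels.
#' @return an [image_grid()] with the volume's sampling.
#' @export
project <- function(vol, azimuth_deg = 0, tilt_deg = 0, psi_deg = 0,
                    shift_px = c(0, 0)) {
  stopifnot(all(is.finite(c(azimuth_deg, tilt_deg, psi_deg, shift_px))))
  n <- dim(vol)[1]
  b <- orientation_basis(azimuth_deg, tilt_deg, psi_deg)
  img <- cpp_project(as.numeric(vol), n, b$u, b$v, b$d,
                     shift_px[1], shift_px[2])
  image_grid(img * apix(vol), apix(vol))
}

#' Rotate an image in plane
#' @param img an [image_grid()] or matrix.
#' @param angle_deg counter-clockwise rotation in degrees.
#' @return rotated image of the same kind.
#' @export
rotate_image <- function(img, angle_deg) {
  out <- cpp_rotate2d(as_plain_array(img), angle_deg * pi / 180)
  a <- attr(img, "apix")
  if (!is.null(a)) image_grid(out, a) else out
}

#' Shift an image by whole pixels
#' @param img image matrix.
#' @param sx,sy integer shifts along u and v (content moves by +sx, +sy).
#' @return shifted image, zeros filled in.
#' @export
shift_image <- function(img, sx, sy) {
  n <- nrow(img)
  out <- matrix(0, n, n)
  sx <- as.integer(round(sx)); sy <- as.integer(round(sy))
  xs <- seq_len(n) - sx; ys <- seq_len(n) - sy
  okx <- xs >= 1 & xs <= n; oky <- ys >= 1 & ys <= n
  out[which(okx), which(oky)] <- img[xs[okx], ys[oky]]
  a <- attr(img, "apix")
  if (!is.null(a)) image_grid(out, a) else out
}

#' Shift an image by a (sub-pixel) offset in Fourier space
#' @param img square image matrix.
#' @param sx,sy shifts along u and v in pixels (content moves by +sx,
#'   +sy; wraps circularly).
#' @return shifted image.
#' @export
fourier_shift <- function(img, sx, sy) {
  n <- nrow(img)
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  px <- exp(-2i * pi * k * sx / n)
  py <- exp(-2i * pi * k * sy / n)
  out <- Re(fft(fft(as_plain_array(img)) * outer(px, py), inverse = TRUE)) / n^2
  a <- attr(img, "apix")
  if (!is.null(a)) image_grid(out, a) else out
}
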