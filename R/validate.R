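# radial |f| grid (1/A) of a cubic volume in natural fft order
vol_freq_grid <- function(n, apix) {
  f2 <- freq_axis_fft(n, apix)^2
  r2 <- outer(f2, f2, `+`)
  sqrt(outer(r2, f2, `+`))       # n x n x n
}

#' Low-pass filter a volume
#'
#' Soft-edged Fourier mask: unity below `1/resolution_ang` minus a
#' two-shell cosine edge, zero above `1/resolution_ang`, so all power
#' beyond the target resolution is removed.
#'
#' @param vol a [volume_grid()].
#' @param resolution_ang target resolution (>= 2 * apix).
#' @return filtered [volume_grid()].
#' @export
lowpass <- function(vol, resolution_ang) {
  n <- dim(vol)[1]
  apx <- apix(vol)
  if (resolution_ang < 2 * apx)
    stop("resolution finer than Nyquist (", 2 * apx, " A)")
  fc <- 1 / resolution_ang
  w <- 2 / (n * apx)                 # two Fourier shells
  f <- vol_freq_grid(n, apx)
  h <- ifelse(f <= fc - w, 1,
              ifelse(f >= fc, 0, 0.5 * (1 + cos(pi * (f - fc + w) / w))))
  out <- Re(fft(fft(as_plain_array(vol)) * h, inverse = TRUE)) / n^3
  volume_grid(array(out, rep(n, 3)), apx)
}

#' Amplitude-correct a reconstruction
#'
#' For reconstructions whose input images were multiplied by their CTFs
#' (phases corrected, amplitudes weighted by CTF^2): divides the Fourier
#' coefficients by `sum CTF^2` (Wiener-guarded), applies the B-factor
#' amplitude term `exp(-B f^2 / 4)` (negative B sharpens), and low-pass
#' filters.  The defaults reproduce a standard post-processing pipeline:
#' B = -2000 A^2 and filtering to 12 A.
#'
#' @param vol a [volume_grid()].
#' @param ctfs list of [ctf_params()] (one per contributing image class).
#' @param bfactor B-factor in A^2 (negative sharpens).
#' @param lowpass_ang final low-pass resolution, or `NULL` to skip.
#' @param wiener_frac Wiener guard as a fraction of the mean `sum CTF^2`.
#' @return corrected [volume_grid()].
#' @export
amplitude_correct <- function(vol, ctfs, bfactor = -2000,
                              lowpass_ang = 12, wiener_frac = 0.1) {
  n <- dim(vol)[1]
  apx <- apix(vol)
  f <- vol_freq_grid(n, apx)
  filt <- exp(-bfactor * f^2 / 4)
  if (length(ctfs) > 0) {
    s2 <- sum_ctf_squared(ctfs, f)
    filt <- filt / (s2 + wiener_frac * mean(s2))
  }
  out <- Re(fft(fft(as_plain_array(vol)) * filt, inverse = TRUE)) / n^3
  out <- volume_grid(array(out, rep(n, 3)), apx)
  if (!is.null(lowpass_ang)) out <- lowpass(out, lowpass_ang)
  out
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized complex correlation (real-valued); identical maps
#' give 1 in every shell and the statistic is exactly symmetric in its
#' arguments.
#'
#' @param map_a,map_b [volume_grid()]s on identical grids.
#' @param shell_width shell width in Fourier voxels.
#' @return data.frame of class `fsc_curve`: `freq` (shell center,
#'   1/Angstrom), `fsc`, `n_voxels`; attributes `apix`, `shell_width`.
#' @export
fsc <- function(map_a, map_b, shell_width = 1) {
  if (!identical(dim(map_a), dim(map_b)) ||
      abs(apix(map_a) - apix(map_b)) > 1e-9)
    stop("maps must share an identical grid")
  n <- dim(map_a)[1]
  apx <- apix(map_a)
  fa <- fft(as_plain_array(map_a))
  fb <- fft(as_plain_array(map_b))
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  shell <- round(sqrt(k2) / shell_width)
  nmax <- floor((n / 2) / shell_width)
  keep <- shell <= nmax & shell >= 1
  sh <- as.integer(shell[keep]) + 1L   # 1-based bins, shell index 1..nmax
  num <- Re(fa * Conj(fb))[keep]
  pa <- Mod(fa)[keep]^2
  pb <- Mod(fb)[keep]^2
  s_num <- tabulate_sum(sh, num, nmax + 1L)
  s_pa <- tabulate_sum(sh, pa, nmax + 1L)
  s_pb <- tabulate_sum(sh, pb, nmax + 1L)
  cnt <- tabulate(sh, nmax + 1L)
  idx <- 2:(nmax + 1L)
  curve <- data.frame(freq = (idx - 1) * shell_width / (n * apx),
                      fsc = s_num[idx] / sqrt(s_pa[idx] * s_pb[idx]),
                      n_voxels = cnt[idx])
  structure(curve, apix = apx, shell_width = shell_width,
            class = c("fsc_curve", "data.frame"))
}

tabulate_sum <- function(bin, val, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(val, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.5, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", ylim = c(-0.1, 1),
                 xlab = "spatial frequency (1/A)", ylab = "FSC", ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the first downward crossing of the threshold, linearly
#' interpolated between shells.  An isolated low shell (a sparse-shell
#' artifact) does not count: the curve must stay below the threshold for
#' `min_run` consecutive shells (or to the end of the curve).  `NA` (the
#' beyond-Nyquist sentinel) when the curve never drops below the
#' threshold.
#'
#' @param curve an [fsc()] result (must start above the threshold).
#' @param threshold FSC threshold (default 0.5).
#' @param min_run consecutive shells required below the threshold.
#' @return resolution in Angstrom, or `NA_real_`.
#' @export
resolution_at <- function(curve, threshold = 0.5, min_run = 2L) {
  if (curve$fsc[1] <= threshold)
    stop("curve does not start above the threshold")
  nsh <- nrow(curve)
  below <- which(vapply(seq_len(nsh), function(i) {
    run <- curve$fsc[i:min(nsh, i + min_run - 1L)]
    all(run < threshold)
  }, logical(1)))
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  f0 <- curve$freq[i - 1]; f1 <- curve$freq[i]
  y0 <- curve$fsc[i - 1]; y1 <- curve$fsc[i]
  fc <- f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0)
  1 / fc
}

#' Rasterize an atomic (or pseudo-atomic) model into a density map
#'
#' Weighted Gaussian rasterization (width `resolution_ang / pi`) followed
#' by a low-pass at the target resolution.  Positions are in Angstrom
#' relative to the box center.
#'
#' @param atoms data.frame with `x`, `y`, `z` (Angstrom) and optionally
#'   `weight` (defaults to 1), e.g. from [read_coordinates()].
#' @param apix_ang sampling of the output grid.
#' @param box_vox cubic box size.
#' @param resolution_ang target resolution.
#' @return a [volume_grid()]; total density equals the summed weights.
#' @export
model_to_map <- function(atoms, apix_ang, box_vox, resolution_ang) {
  w <- if (is.null(atoms$weight)) rep(1, nrow(atoms)) else atoms$weight
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  half <- box_vox * apix_ang / 2
  out_of_box <- which(apply(abs(pos) > half - apix_ang, 1, any))
  if (length(out_of_box) > 0)
    stop("atoms outside the box: rows ",
         paste(head(out_of_box, 10), collapse = ", "),
         if (length(out_of_box) > 10) " ..." else "")
  sigma <- resolution_ang / pi
  dat <- cpp_rasterize_gauss(box_vox, apix_ang, pos, w, sigma)
  vol <- volume_grid(array(dat, rep(box_vox, 3)), apix_ang)
  lowpass(vol, resolution_ang)
}

#' Cylindrically average a volume about the helix axis
#'
#' Mean density per (radius, z) bin, bin width one voxel; invariant (to
#' interpolation accuracy) under rotation of the input about z.
#'
#' @param vol a [volume_grid()] with the helix axis along z.
#' @return object of class `cyl_profile`: matrix (radius x z) with
#'   attributes `radius_ang`, `z_ang`, `counts` (voxels per radius bin)
#'   and `apix`.
#' @export
cylindrical_average <- function(vol) {
  n <- dim(vol)[1]
  apx <- apix(vol)
  ax <- seq_len(n) - 1 - floor(n / 2)
  r <- sqrt(outer(ax^2, ax^2, `+`))
  bin <- pmin(round(r), n %/% 2 - 1L) + 1L
  nb <- n %/% 2
  M <- matrix(as.numeric(vol), n * n, n)
  sums <- rowsum(M, as.integer(bin))
  cnt <- tabulate(bin, nb)
  prof <- sums[seq_len(nb), , drop = FALSE] / cnt
  structure(prof, radius_ang = (seq_len(nb) - 1) * apx,
            z_ang = ax * apx, counts = cnt, apix = apx,
            class = "cyl_profile")
}

#' @export
print.cyl_profile <- function(x, ...) {
  cat(sprintf("<cyl_profile> %d radius bins x %d z slices, %.3g A/bin\n",
              nrow(x), ncol(x), attr(x, "apix")))
  invisible(x)
}

#' Axial-hole metric of a cylindrical profile
#'
#' Ratio of the mean density in the axial core (radius < `r_core_ang`,
#' all z, voxel-weighted) to the maximum over radius of the z-averaged
#' density.  A solid cylinder scores about 1, a hollow filament well below
#' it; helically arranged subunits filtered to intermediate resolution
#' show a continuous central hole and score low.
#'
#' @param profile a [cylindrical_average()] result.
#' @param r_core_ang core radius in Angstrom.
#' @return non-negative ratio.
#' @export
axial_hole_metric <- function(profile, r_core_ang = 5) {
  stopifnot(nrow(profile) > 0)
  radius <- attr(profile, "radius_ang")
  cnt <- attr(profile, "counts")
  core <- radius < r_core_ang
  if (!any(core)) stop("no radius bins inside r_core_ang")
  core_mean <- sum(profile[core, , drop = FALSE] * cnt[core]) /
    (sum(cnt[core]) * ncol(profile))
  radial <- rowMeans(profile)
  mx <- max(radial)
  if (mx <= 0) stop("profile maximum is not positive; ratio undefined")
  core_mean / mx
}

#' Align a helical volume to a reference over the gauge freedom
#'
#' A helical reconstruction is only determined up to a rotation about and
#' a translation along its axis (the lattice gauge).  Before comparing a
#' reconstruction to a reference map (e.g. by [fsc()]), this searches that
#' rotation/translation for the maximum masked real-space correlation,
#' coarse grid first, then local refinement.
#'
#' @param vol [volume_grid()] to align.
#' @param ref reference [volume_grid()] on the same grid.
#' @param mask_radius_ang cylindrical mask radius (default box/3).
#' @param z_frac central axial fraction compared.
#' @param max_shift_ang translation search half-range in Angstrom.
#' @param rot_step_deg,shift_step_ang coarse grid steps.
#' @return the aligned [volume_grid()] with attributes `rotation_deg`,
#'   `shift_ang` and `correlation`.
#' @export
align_helical_volume <- function(vol, ref, mask_radius_ang = NULL,
                                 z_frac = 0.6, max_shift_ang = 10,
                                 rot_step_deg = 4, shift_step_ang = 2) {
  stopifnot(identical(dim(vol), dim(ref)))
  n <- dim(vol)[1]
  apx <- apix(vol)
  if (is.null(mask_radius_ang)) mask_radius_ang <- n * apx / 3
  ax <- seq_len(n) - 1 - floor(n / 2)
  in_mask <- outer(ax^2, ax^2, `+`) <= (mask_radius_ang / apx)^2
  band <- seq.int(ceiling((n - 1) * (0.5 - z_frac / 2)) + 1L,
                  floor((n - 1) * (0.5 + z_frac / 2)) + 1L)
  sel <- rep(in_mask, length(band))
  rv <- as_plain_array(ref)[, , band][sel]
  rv <- rv - mean(rv)
  rn <- sqrt(sum(rv^2))
  score <- function(ang, dz) {
    tv <- cpp_zrot_shift(as.numeric(vol), n, ang * pi / 180, dz / apx)
    dim(tv) <- rep(n, 3)
    x <- tv[, , band][sel]
    x <- x - mean(x)
    s <- sqrt(sum(x^2))
    if (s < 1e-12) return(-1)
    sum(x * rv) / (s * rn)
  }
  best <- c(0, 0); bc <- -2
  for (ang in seq(0, 360 - rot_step_deg, by = rot_step_deg))
    for (dz in seq(-max_shift_ang, max_shift_ang, by = shift_step_ang)) {
      cc <- score(ang, dz)
      if (cc > bc) { bc <- cc; best <- c(ang, dz) }
    }
  da <- rot_step_deg; dzs <- shift_step_ang
  while (da > 0.2 || dzs > 0.1) {
    da <- max(da / 2, 0.1); dzs <- max(dzs / 2, 0.05)
    cand <- expand.grid(a = best[1] + da * (-1:1), z = best[2] + dzs * (-1:1))
    cc <- mapply(score, cand$a, cand$z)
    i <- which.max(cc)
    if (cc[i] > bc) { bc <- cc[i]; best <- c(cand$a[i], cand$z[i]) }
  }
  out <- cpp_zrot_shift(as.numeric(vol), n, best[1] * pi / 180,
                        best[2] / apx)
  structure(volume_grid(array(out, rep(n, 3)), apx),
            rotation_deg = best[1], shift_ang = best[2], correlation = bc)
}
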