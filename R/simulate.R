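#' Gaussian blob model of a filament subunit
#'
#' A pseudo-atomic stand-in for a protein subunit: one or more Gaussian
#' blobs with centers given in Angstrom in a frame whose z axis is the
#' helix axis and whose origin lies on the axis.
#'
#' @param centers numeric matrix (m x 3) of blob centers in Angstrom.
#' @param sigma_ang Gaussian width in Angstrom (> 0).
#' @param weights per-blob densities (recycled).
#' @return object of class `blob_model`.
#' @export
blob_model <- function(centers, sigma_ang = 8, weights = 1) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) < 1L) stop("at least one blob center is required")
  if (sigma_ang <= 0) stop("sigma_ang must be > 0")
  weights <- rep_len(weights, nrow(centers))
  structure(list(centers = centers, sigma_ang = sigma_ang,
                 weights = weights),
            class = "blob_model")
}

#' @rdname blob_model
#' @param radius_ang helical radius of the single default blob.
#' @export
default_subunit <- function(radius_ang = 30, sigma_ang = 8) {
  blob_model(matrix(c(radius_ang, 0, 0), 1), sigma_ang = sigma_ang)
}

#' Build a helical filament volume from a subunit model
#'
#' Sums symmetry-transformed copies of the subunit blobs on a cubic grid,
#' helix axis along z through the box center.  Subunits are centered
#' axially about the middle of the box.
#'
#' @param sym a [helical_symmetry()].
#' @param subunit a [blob_model()].
#' @param box_vox cubic box size in voxels.
#' @param apix_ang sampling in Angstrom per voxel.
#' @param n_subunits number of helical repeats (per Cn copy); default fills
#'   the box with a 2-sigma margin.
#' @return a [volume_grid()].
#' @export
build_filament_volume <- function(sym, subunit = default_subunit(),
                                  box_vox = 96, apix_ang = 2.3,
                                  n_subunits = NULL) {
  sym <- as_helical_symmetry(sym)
  half <- box_vox * apix_ang / 2
  zext <- max(abs(subunit$centers[, 3]))
  if (is.null(n_subunits)) {
    n_subunits <- 2L * floor((half - 2 * subunit$sigma_ang - zext) /
                               sym$rise_ang) + 1L
    n_subunits <- max(n_subunits, 1L)
  }
  kh <- (n_subunits - 1) / 2
  span <- kh * sym$rise_ang + zext + 2 * subunit$sigma_ang
  if (span > half)
    stop("filament overflows the box: ", n_subunits,
         " subunits need a half-length of ", round(span, 1), " A > ",
         round(half, 1), " A")
  ops <- symmetry_operators(sym, k_min = -ceiling(kh), k_max = floor(kh))
  ang <- ops$rotation_deg * pi / 180
  ctr <- NULL; wts <- NULL
  for (i in seq_len(nrow(ops))) {
    R <- matrix(c(cos(ang[i]), sin(ang[i]), 0,
                  -sin(ang[i]), cos(ang[i]), 0,
                  0, 0, 1), 3, 3)
    p <- subunit$centers %*% t(R)
    p[, 3] <- p[, 3] + ops$translation_ang[i]
    ctr <- rbind(ctr, p)
    wts <- c(wts, subunit$weights)
  }
  dat <- cpp_rasterize_gauss(box_vox, apix_ang, ctr, wts,
                             subunit$sigma_ang)
  volume_grid(array(dat, rep(box_vox, 3)), apix_ang)
}

#' Overlapping segment window offsets
#'
#' Offsets (in pixels, starting at 0) of overlapping windows of length
#' `window_px` stepped by `shift_px` along a filament of length
#' `filament_length_px`; the count is `floor((L - w)/s) + 1`.  With the
#' 192 px / 6 px defaults consecutive windows overlap by 97 percent.
#'
#' @param filament_length_px filament box length L in pixels.
#' @param window_px segment window length w.
#' @param shift_px step s between windows (>= 1).
#' @return integer vector of offsets (empty, with a warning, when L < w).
#' @export
extract_segments <- function(filament_length_px, window_px = 192,
                             shift_px = 6) {
  stopifnot(shift_px >= 1, window_px >= 1)
  if (filament_length_px < window_px) {
    warning("filament shorter than the segment window; no segments")
    return(integer(0))
  }
  seq.int(0L, by = as.integer(shift_px),
          length.out = floor((filament_length_px - window_px) / shift_px) + 1L)
}

#' @rdname extract_segments
#' @return `segment_overlap` returns the fractional overlap of consecutive
#'   windows, `(w - s)/w`.
#' @export
segment_overlap <- function(window_px = 192, shift_px = 6) {
  (window_px - shift_px) / window_px
}

# draw from a truncated normal by rejection (exact given the seed stream)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Soft mask for a vertical filament (weights in [0,1]): a band of
# half-width radius_px across the filament, optionally restricted to the
# central v_frac of the axial extent (so reference projections whose
# tilted ends leave the box are compared only where density is complete).
filament_mask <- function(n, radius_px, edge_px = 3, v_frac = 1) {
  soft <- function(d, r) ifelse(d <= r, 1,
                                ifelse(d >= r + edge_px, 0,
                                       0.5 * (1 + cos(pi * (d - r) / edge_px))))
  u <- abs(seq_len(n) - 1 - floor(n / 2))
  w <- soft(u, radius_px)
  m <- matrix(rep(w, n), n, n)
  if (v_frac < 1) {
    v <- soft(u, v_frac * n / 2)
    m <- m * matrix(rep(v, each = n), n, n)
  }
  m
}

# low-frequency-boosted noise field mimicking a carbon-film background
carbon_noise_field <- function(n, apix, f0 = 1 / 50) {
  white <- matrix(rnorm(n * n), n, n)
  f <- ctf_freq_grid(n, apix)
  h <- 1 / (1 + (f / f0)^2)
  x <- Re(fft(fft(white) * h, inverse = TRUE)) / n^2
  x / sd(x)
}

#' Simulate a helical cryo-EM segment dataset with ground truth
#'
#' Emulates the imaging conditions of low-dose filament data: filaments lie
#' near the specimen plane but with substantial out-of-plane tilt (truncated
#' normal), azimuth uniform, small in-plane rotations, defocus drawn from a
#' truncated normal spanning 1.7-5.4 um with mean 3.2 um, CTF-multiplied
#' projections, and additive white Gaussian noise calibrated so that the
#' signal-to-noise ratio (variance ratio inside the filament mask) equals
#' `snr`.  Segments along one filament share tilt, psi and defocus; the
#' axial window step advances the azimuth through the helical lattice
#' (a step of t Angstrom equals `round(t/rise)` subunit twists plus a
#' sub-rise axial shift).  Everything is reproducible from `seed`.
#'
#' @param sym generating [helical_symmetry()].
#' @param subunit a [blob_model()].
#' @param n_filaments number of filaments.
#' @param segments_per_filament overlapping windows per filament.
#' @param box_px segment box size in pixels.
#' @param apix_ang sampling, Angstrom per pixel.
#' @param window_shift_px axial step between overlapping windows.
#' @param tilt_sigma_deg,tilt_max_deg truncated-normal out-of-plane tilt.
#' @param psi_sigma_deg in-plane rotation spread.
#' @param defocus_range_um,defocus_mean_um,defocus_sd_um truncated-normal
#'   defocus draw.
#' @param snr signal-to-noise variance ratio (> 0).
#' @param carbon_noise relative amplitude (vs the white noise sd) of an
#'   extra low-frequency background field; 0 disables it.
#' @param jitter_px uniform random residual shift added per segment.
#' @param seed master random seed (required).
#' @return list of class `helix_sim` with `stack` (box x box x n array,
#'   `apix` attribute), `truth` (one row per segment: identifiers, true
#'   orientation, shifts, CTF parameters), `volume` (the clean generating
#'   volume), `sym`, `config`, `seed`.
#' @export
simulate_dataset <- function(sym, subunit = default_subunit(),
                             n_filaments = 10, segments_per_filament = 10,
                             box_px = 192, apix_ang = 2.3,
                             window_shift_px = 6,
                             tilt_sigma_deg = 12, tilt_max_deg = 35,
                             psi_sigma_deg = 2,
                             defocus_range_um = c(1.7, 5.4),
                             defocus_mean_um = 3.2, defocus_sd_um = 0.8,
                             snr = 0.1, carbon_noise = 0, jitter_px = 1,
                             seed) {
  if (missing(seed)) stop("a master seed is required")
  if (snr <= 0) stop("snr must be > 0")
  if (tilt_max_deg < 0 || tilt_sigma_deg < 0)
    stop("impossible tilt configuration")
  sym <- as_helical_symmetry(sym)
  set.seed(seed)
  vol <- build_filament_volume(sym, subunit, box_px, apix_ang)
  nseg <- n_filaments * segments_per_filament
  stack <- array(0, c(box_px, box_px, nseg))
  mask <- filament_mask(box_px,
                        radius_px = (max(sqrt(rowSums(subunit$centers[, 1:2,
                                                                      drop = FALSE]^2))) +
                                       2 * subunit$sigma_ang) / apix_ang)
  offsets <- extract_segments(box_px + (segments_per_filament - 1) *
                                window_shift_px, box_px, window_shift_px)
  truth <- vector("list", nseg)
  s <- 0L
  for (fil in seq_len(n_filaments)) {
    az0 <- runif(1, 0, 360)
    tilt <- rtruncnorm1(1, 0, tilt_sigma_deg, -tilt_max_deg, tilt_max_deg)
    psi <- rnorm(1, 0, psi_sigma_deg)
    dfc <- rtruncnorm1(1, defocus_mean_um, defocus_sd_um,
                       defocus_range_um[1], defocus_range_um[2])
    ctf <- ctf_params(defocus_um = dfc, apix_ang = apix_ang)
    for (o in offsets) {
      s <- s + 1L
      t_ang <- o * apix_ang
      kk <- round(t_ang / sym$rise_ang)
      az <- (az0 + kk * sym$twist_deg) %% 360
      sx <- runif(1, -jitter_px, jitter_px)
      sy <- (t_ang - kk * sym$rise_ang) / apix_ang +
        runif(1, -jitter_px, jitter_px)
      img <- project(vol, az, tilt, psi, shift_px = c(sx, sy))
      img <- apply_ctf(img, ctf, mode = "multiply")
      sig_var <- sum(mask * (img - sum(mask * img) / sum(mask))^2) /
        sum(mask)
      nsd <- sqrt(sig_var / snr)
      noisy <- img + rnorm(box_px^2, 0, nsd)
      if (carbon_noise > 0)
        noisy <- noisy + carbon_noise * nsd *
          carbon_noise_field(box_px, apix_ang)
      stack[, , s] <- noisy
      truth[[s]] <- data.frame(
        segment_id = s, filament_id = fil, box_px = box_px,
        apix_ang = apix_ang, azimuth_deg = az, tilt_deg = tilt,
        psi_deg = psi, shift_x_px = sx, shift_y_px = sy,
        defocus_um = dfc, cs_mm = ctf$cs_mm, kv = ctf$kv,
        amp_contrast = ctf$amp_contrast, orientation = "true")
    }
  }
  truth <- do.call(rbind, truth)
  attr(stack, "apix") <- apix_ang
  class(stack) <- "image_stack"
  structure(list(stack = stack, truth = truth, volume = vol, sym = sym,
                 config = list(n_filaments = n_filaments,
                               segments_per_filament = segments_per_filament,
                               box_px = box_px, apix_ang = apix_ang,
                               window_shift_px = window_shift_px,
                               tilt_sigma_deg = tilt_sigma_deg,
                               tilt_max_deg = tilt_max_deg,
                               psi_sigma_deg = psi_sigma_deg,
                               defocus_range_um = defocus_range_um,
                               defocus_mean_um = defocus_mean_um,
                               defocus_sd_um = defocus_sd_um,
                               snr = snr, carbon_noise = carbon_noise,
                               jitter_px = jitter_px),
                 seed = seed),
            class = "helix_sim")
}

#' @export
print.helix_sim <- function(x, ...) {
  cat(sprintf(
    "<helix_sim> %d segments (%d filaments), box %d px @ %.3g A/px, snr %.3g\n",
    dim(x$stack)[3], x$config$n_filaments, x$config$box_px,
    x$config$apix_ang, x$config$snr))
  print(x$sym)
  invisible(x)
}

#' Write / read a ground-truth or assignment table as TSV
#' @param truth data.frame of per-segment records.
#' @param path file path.
#' @return `read_truth_tsv` returns the data.frame.
#' @export
write_truth_tsv <- function(truth, path) write_tsv_table(truth, path)

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) read_tsv_table(path)
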