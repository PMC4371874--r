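#' Impose helical symmetry on a volume
#'
#' Replaces each voxel by the average of the volume over the helical
#' symmetry operators (k * twist, k * rise) combined with Cn rotational
#' averaging, drawing source density only from the central axial band of
#' the box (to avoid end/wrap artifacts) and zeroing voxels outside a
#' cylindrical mask.
#'
#' @param vol a [volume_grid()].
#' @param sym a [helical_symmetry()].
#' @param mask_radius_ang cylinder mask radius (default box/3).
#' @param z_frac fraction of the axial extent treated as valid source
#'   density (default 0.6, centered).
#' @param max_ops bound on the operator index |k| averaged per voxel.
#'   Averaging over many operators is only as good as the symmetry
#'   estimate: a rise error dr misregisters the k-th copy by k * dr, so
#'   the default (12) trades noise averaging against axial smearing when
#'   (twist, rise) are themselves being refined.
#' @return symmetrized [volume_grid()].
#' @export
impose_helical_symmetry <- function(vol, sym, mask_radius_ang = NULL,
                                    z_frac = 0.6, max_ops = 12L) {
  sym <- as_helical_symmetry(sym)
  n <- dim(vol)[1]
  apx <- apix(vol)
  if (is.null(mask_radius_ang)) mask_radius_ang <- n * apx / 3
  if (mask_radius_ang > n * apx / 2)
    stop("mask radius exceeds the box half-width")
  band <- z_frac * n * apx
  if (band < 3 * sym$rise_ang)
    stop("axial band too short for three symmetry copies")
  rise_vox <- sym$rise_ang / apx
  zlo <- (n - 1) * (0.5 - z_frac / 2)
  zhi <- (n - 1) * (0.5 + z_frac / 2)
  kmax <- min(ceiling((n - 1 - zlo) / rise_vox), as.integer(max_ops))
  dat <- cpp_symmetrize(as.numeric(vol), n, sym$twist_deg * pi / 180,
                        rise_vox, kmax, sym$cn_order,
                        mask_radius_ang / apx, zlo, zhi)
  volume_grid(array(dat, rep(n, 3)), apx)
}

#' Search the helical symmetry of a volume
#'
#' Minimizes the masked mean-squared difference between the volume and its
#' copy transformed by one forward helical operator over a (twist, rise)
#' window: a coarse grid scan followed by local pattern refinement down to
#' `refine_tol`.  A featureless volume (flat residual surface, e.g. a
#' solid cylinder) raises a `degenerate_search` error rather than
#' returning a meaningless answer.
#'
#' @param vol a [volume_grid()].
#' @param twist_window,rise_window numeric `c(lo, hi)` search windows
#'   (degrees, Angstrom).
#' @param coarse_steps grid points per axis for the coarse scan.
#' @param refine_tol c(twist, rise) refinement tolerances.
#' @param mask_radius_ang cylinder mask radius (default box/3).
#' @param z_frac central axial fraction compared.
#' @param baseline_vol optional noise-baseline volume (e.g. a
#'   back-projection of the same segments with scrambled azimuths): its
#'   residual surface is subtracted before minimization, cancelling the
#'   systematic preference of correlated noise for small operators.
#' @param n_ops average the mismatch over operator powers k = 1..n_ops.
#'   A twist error e misregisters the k-th copy by k*e, so chaining
#'   operators sharpens the twist (and rise) sensitivity roughly
#'   n_ops-fold -- decisive on noisy reconstructions.
#' @return list with `twist_deg`, `rise_ang`, `residual` (masked MSE at
#'   the optimum) and `surface` (coarse residual matrix, twist x rise).
#' @export
hsearch <- function(vol, twist_window, rise_window,
                    coarse_steps = c(11, 11), refine_tol = c(0.01, 0.01),
                    mask_radius_ang = NULL, z_frac = 0.6,
                    baseline_vol = NULL, n_ops = 1L) {
  n <- dim(vol)[1]
  apx <- apix(vol)
  if (is.null(mask_radius_ang)) mask_radius_ang <- n * apx / 3
  if (diff(twist_window) <= 0 || diff(rise_window) <= 0)
    stop("search windows must be non-degenerate")
  if (rise_window[1] <= 0) rise_window[1] <- min(apx / 10, rise_window[2] / 10)
  zlo <- (n - 1) * (0.5 - z_frac / 2)
  zhi <- (n - 1) * (0.5 + z_frac / 2)
  mr <- mask_radius_ang / apx
  v <- as.numeric(vol)
  vb <- if (is.null(baseline_vol)) NULL else as.numeric(baseline_vol)
  band_vox <- zhi - zlo
  ks <- seq_len(max(1L, as.integer(n_ops)))
  eval_on <- function(vv) function(tw, ri) {
    kk <- ks[ks * ri / apx <= band_vox / 2]
    if (length(kk) == 0L) kk <- 1L
    mean(vapply(kk, function(k)
      cpp_helical_residual(vv, n, k * tw * pi / 180, k * ri / apx,
                           mr, zlo, zhi)[1], numeric(1)))
  }
  eval_raw <- eval_on(v)
  eval1 <- if (is.null(vb)) eval_raw else function(tw, ri)
    eval_raw(tw, ri) - eval_on(vb)(tw, ri)
  tws <- seq(twist_window[1], twist_window[2], length.out = coarse_steps[1])
  ris <- seq(rise_window[1], rise_window[2], length.out = coarse_steps[2])
  surf_raw <- outer(tws, ris, Vectorize(eval_raw))
  surf <- if (is.null(vb)) surf_raw else outer(tws, ris, Vectorize(eval1))
  dimnames(surf) <- list(twist = signif(tws, 6), rise = signif(ris, 6))
  # Degeneracy: an axially featureless volume (e.g. a solid cylinder) has
  # a residual independent of the rise -- only rotation-interpolation
  # noise varies across twist rows -- so the rise variation within twist
  # rows is the discriminating signal (checked on the raw surface).
  row_rng <- apply(surf_raw, 1, function(r) max(r) - min(r))
  if (!all(is.finite(surf_raw)) || max(surf_raw) <= 0 ||
      max(row_rng) <= 1e-3 * max(surf_raw))
    stop(structure(class = c("degenerate_search", "error", "condition"),
                   list(message = paste0(
                     "degenerate symmetry search: residual surface is flat ",
                     "(featureless volume?)"), call = sys.call(-1))))
  best <- which(surf == min(surf), arr.ind = TRUE)[1, ]
  tw <- tws[best[1]]; ri <- ris[best[2]]
  res <- surf[best[1], best[2]]
  dt <- diff(tws[1:2]); dr <- diff(ris[1:2])
  while (dt > refine_tol[1] || dr > refine_tol[2]) {
    dt <- max(dt / 2, refine_tol[1] / 2)
    dr <- max(dr / 2, refine_tol[2] / 2)
    cand <- expand.grid(tw = tw + dt * (-1:1), ri = ri + dr * (-1:1))
    cand <- cand[cand$ri > 0 &
                   cand$tw >= twist_window[1] & cand$tw <= twist_window[2] &
                   cand$ri >= rise_window[1] & cand$ri <= rise_window[2], ]
    rv <- mapply(eval1, cand$tw, cand$ri)
    i <- which.min(rv)
    if (rv[i] < res) { tw <- cand$tw[i]; ri <- cand$ri[i]; res <- rv[i] }
  }
  list(twist_deg = tw, rise_ang = ri, residual = res, surface = surf)
}

#' Back-project assigned segments into a volume
#'
#' Aligns each segment into the reference frame (undoing its assigned psi
#' and shifts), optionally applies a one-dimensional ramp filter across the
#' filament axis (the classical weighting for views distributed about a
#' single axis), and smears each image along its viewing direction into the
#' volume; the accumulation is normalized by the segment count.
#'
#' @param segments 3-D stack (n x n x m) with an `apix` attribute, or a
#'   single [image_grid()].
#' @param assignments data.frame as returned by [match_segments()] (or a
#'   truth table): `azimuth_deg`, `tilt_deg`, `psi_deg`, `shift_x_px`,
#'   `shift_y_px` per segment.
#' @param apix_ang sampling override.
#' @param ramp logical: apply the ramp weighting.
#' @return a [volume_grid()] of the segment box size.
#' @export
back_project <- function(segments, assignments, apix_ang = NULL,
                         ramp = TRUE) {
  if (length(dim(segments)) == 2L)
    segments <- array(as_plain_array(segments), c(dim(segments), 1))
  if (is.null(apix_ang)) apix_ang <- attr(segments, "apix")
  n <- dim(segments)[1]
  m <- dim(segments)[3]
  if (m < 1L) stop("no segments to back-project")
  if (nrow(assignments) != m)
    stop("assignment table does not match the segment count")
  wk <- NULL
  if (ramp) {
    k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
    wk <- pmax(abs(k), 0.5) * 2 / n
  }
  acc <- numeric(n^3)
  for (i in seq_len(m)) {
    img <- segments[, , i]
    psi <- assignments$psi_deg[i]
    sx <- assignments$shift_x_px[i]; sy <- assignments$shift_y_px[i]
    if (psi != 0) img <- cpp_rotate2d(img, -psi * pi / 180)
    if (sx != 0 || sy != 0) img <- fourier_shift(img, -sx, -sy)
    if (ramp) img <- Re(fft(fft(img) * wk, inverse = TRUE)) / n^2
    b <- orientation_basis(assignments$azimuth_deg[i],
                           assignments$tilt_deg[i], 0)
    cpp_backproject(acc, img, n, b$u, b$v)
  }
  volume_grid(array(acc / m, rep(n, 3)), apix_ang)
}

#' Decimate an image, stack or volume by Fourier cropping
#'
#' Crops the centered Fourier transform to `1/factor` of its extent: the
#' sampling becomes `apix * factor` and the mean (DC term) is preserved
#' exactly.
#'
#' @param x [image_grid()], [volume_grid()] or image stack.
#' @param factor integer >= 1 dividing the box size.
#' @return same kind of object at the coarser sampling.
#' @export
decimate <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(x)
  d <- dim(x)
  apx <- attr(x, "apix")
  stack <- length(d) == 3L &&
    (inherits(x, "image_stack") || length(unique(d)) != 1L)
  nd <- if (stack) d[1:2] else d
  if (any(nd %% factor != 0))
    stop("decimation factor must divide the box size")
  crop1 <- function(arr) {
    dd <- dim(arr)
    ft <- fftshift(fft(arr))
    idx <- lapply(dd, function(nn) {
      mm <- nn %/% factor
      (floor(nn / 2) - floor(mm / 2) + 1):(floor(nn / 2) - floor(mm / 2) + mm)
    })
    ft <- do.call(`[`, c(list(ft), idx, list(drop = FALSE)))
    Re(fft(ifftshift(ft), inverse = TRUE)) / prod(dd)
  }
  if (stack) {
    m <- d[3]
    nn <- d[1] %/% factor
    out <- array(0, c(nn, nn, m))
    for (i in seq_len(m)) out[, , i] <- crop1(x[, , i])
    attr(out, "apix") <- apx * factor
    class(out) <- "image_stack"
    return(out)
  }
  out <- crop1(as_plain_array(x))
  if (length(d) == 2L) image_grid(out, apx * factor)
  else volume_grid(out, apx * factor)
}

# soft-edged solid cylinder initial reference
solid_cylinder <- function(n, apix_ang, radius_ang, edge_px = 3) {
  r <- sqrt(outer((seq_len(n) - 1 - floor(n / 2))^2,
                  (seq_len(n) - 1 - floor(n / 2))^2, `+`)) # voxels
  rpx <- radius_ang / apix_ang
  prof <- ifelse(r <= rpx, 1,
                 ifelse(r >= rpx + edge_px, 0,
                        0.5 * (1 + cos(pi * (r - rpx) / edge_px))))
  volume_grid(array(rep(prof, n), rep(n, 3)), apix_ang)
}

#' Options for the IHRSR loop
#'
#' @param azimuth_step_deg reference azimuth increment per cycle.
#' @param tilt_aware include out-of-plane tilt in the reference grid.
#' @param ref_tilt_max_deg,ref_tilt_step_deg tilt grid when `tilt_aware`.
#' @param psi_search_deg,psi_step_deg,shift_search_px,shift_step_px
#'   alignment search (see [match_segments()]).
#' @param twist_window_deg,rise_window_ang half-widths of the symmetry
#'   search window around the current estimate.
#' @param coarse_steps,refine_tol passed to [hsearch()].
#' @param mask_radius_ang cylindrical mask; the default
#'   (`cylinder_radius_ang + 2 * apix`) hugs the filament, which keeps
#'   reconstruction noise out of the symmetry search.
#' @param hsearch_lowpass_ang low-pass applied to the reconstruction
#'   before the symmetry search (suppresses the white-noise floor that
#'   otherwise biases the search toward small operators); default
#'   3 x apix.
#' @param z_frac axial band used for symmetrization and the search.
#' @param decimate_factor,decimated_cycles run the first cycles at
#'   `factor`-times coarser sampling, ignoring these settings when 1/0.
#' @param init_volume `"solid_cylinder"` or a [volume_grid()] to start
#'   from.
#' @param cylinder_radius_ang radius of the solid-cylinder start.
#' @param hold_sym_cycles cycles during which a degenerate symmetry search
#'   is tolerated (symmetry held fixed) when starting from a cylinder.
#' @param ramp ramp-filter back-projections.
#' @param noise_baseline subtract a scrambled-azimuth noise baseline in
#'   the per-cycle symmetry search (see [hsearch()]).
#' @param ref_lowpass_ang low-pass applied to the working volume before
#'   reference projections are made (default 4 x apix): matching against
#'   filtered references suppresses the noise model-bias that otherwise
#'   builds up when segments are re-matched against a reconstruction of
#'   themselves.
#' @return list of class `ihrsr_options`.
#' @export
ihrsr_options <- function(azimuth_step_deg = 6, tilt_aware = FALSE,
                          ref_tilt_max_deg = 16, ref_tilt_step_deg = 8,
                          psi_search_deg = 4, psi_step_deg = 2,
                          shift_search_px = 2, shift_step_px = 1,
                          twist_window_deg = 2, rise_window_ang = 0.4,
                          coarse_steps = c(9, 9),
                          refine_tol = c(0.01, 0.01),
                          mask_radius_ang = NULL,
                          hsearch_lowpass_ang = NULL,
                          hsearch_n_ops = 8, z_frac = 0.6,
                          decimate_factor = 1, decimated_cycles = 0,
                          init_volume = "solid_cylinder",
                          cylinder_radius_ang = 40,
                          hold_sym_cycles = 3, ramp = TRUE,
                          noise_baseline = TRUE,
                          ref_lowpass_ang = NULL) {
  stopifnot(decimate_factor >= 1, twist_window_deg > 0,
            rise_window_ang > 0)
  structure(as.list(environment()), class = "ihrsr_options")
}

#' Iterative helical real-space reconstruction (IHRSR)
#'
#' The full refinement loop: from the current (symmetrized) volume build
#' reference projections over azimuth (and optionally out-of-plane tilt),
#' assign every segment by normalized cross-correlation, back-project,
#' search the helical symmetry of the new volume in a window around the
#' current estimate, impose it, and repeat.  Early cycles can run on
#' decimated images; segments are expected to have been CTF-corrected
#' (multiplied) upstream.  The per-cycle (twist, rise) trajectory is the
#' primary diagnostic: a stable trajectory is necessary but not sufficient
#' for the symmetry to be correct.
#'
#' @param segments 3-D segment stack (n x n x m) with an `apix` attribute.
#' @param init_sym starting [helical_symmetry()] (or `c(twist, rise)` /
#'   `c(twist, rise, cn)`).
#' @param cycles refinement cycles.
#' @param opts an [ihrsr_options()] list.
#' @param apix_ang sampling override.
#' @param seed random seed recorded with the run (the loop itself is
#'   deterministic).
#' @param verbose print per-cycle progress.
#' @return object of class `ihrsr` with components `trajectory` (cycle,
#'   twist_deg, rise_ang, residual, mean_cc), `sym` (final
#'   [helical_symmetry()]), `volume` (final symmetrized [volume_grid()]),
#'   `assignments`, `opts`, `converged`, `seed`.  Methods: `print`,
#'   `summary`, `coef`, `plot`, `predict`.
#' @seealso [hsearch()], [impose_helical_symmetry()], [back_project()]
#' @export
ihrsr <- function(segments, init_sym, cycles = 8, opts = ihrsr_options(),
                  apix_ang = NULL, seed = 1, verbose = FALSE) {
  if (is.null(apix_ang)) apix_ang <- attr(segments, "apix")
  if (is.null(apix_ang)) stop("segments carry no apix and none was given")
  if (!inherits(segments, "image_stack")) {
    attr(segments, "apix") <- apix_ang
    class(segments) <- "image_stack"
  }
  set.seed(seed)
  sym <- as_helical_symmetry(init_sym)
  n_full <- dim(segments)[1]
  fac <- opts$decimate_factor
  ndec <- if (fac > 1) opts$decimated_cycles else 0
  stk_d <- if (ndec > 0) decimate(segments, fac) else NULL
  cyl_init <- identical(opts$init_volume, "solid_cylinder")
  make_init <- function(stk, apx) {
    if (cyl_init)
      solid_cylinder(dim(stk)[1], apx, opts$cylinder_radius_ang)
    else {
      v <- opts$init_volume
      if (!inherits(v, "volume_grid")) stop("init_volume must be a volume_grid")
      if (dim(v)[1] != dim(stk)[1]) decimate(v, dim(v)[1] %/% dim(stk)[1])
      else v
    }
  }
  traj <- data.frame(cycle = 0L, twist_deg = sym$twist_deg,
                     rise_ang = sym$rise_ang, residual = NA_real_,
                     mean_cc = NA_real_)
  vol_work <- NULL
  asn <- NULL
  prev_dec <- NA
  for (cy in seq_len(cycles)) {
    dec <- cy <= ndec
    stk <- if (dec) stk_d else segments
    apx <- if (dec) apix_ang * fac else apix_ang
    nb <- dim(stk)[1]
    mask_ang <- if (is.null(opts$mask_radius_ang))
      min(opts$cylinder_radius_ang + 2 * apx, nb * apx / 2 - 2 * apx)
    else opts$mask_radius_ang
    hs_lp <- if (is.null(opts$hsearch_lowpass_ang)) 4 * apx
             else opts$hsearch_lowpass_ang
    if (is.null(vol_work)) {
      vol_work <- impose_helical_symmetry(make_init(stk, apx), sym,
                                          mask_ang, opts$z_frac)
    } else if (!identical(dec, prev_dec)) {
      # sampling regime change: rebuild from the last assignments
      asn_f <- asn
      asn_f$shift_x_px <- asn_f$shift_x_px * fac
      asn_f$shift_y_px <- asn_f$shift_y_px * fac
      vol_work <- impose_helical_symmetry(
        back_project(stk, asn_f, apx, ramp = opts$ramp), sym,
        mask_ang, opts$z_frac)
    }
    prev_dec <- dec
    tilt_max <- if (opts$tilt_aware && !dec) opts$ref_tilt_max_deg else 0
    tilt_step <- if (tilt_max > 0) opts$ref_tilt_step_deg else 4
    ref_lp <- if (is.null(opts$ref_lowpass_ang)) 4 * apx
              else opts$ref_lowpass_ang
    refs <- make_reference_set(
      if (ref_lp >= 2 * apx) lowpass(vol_work, ref_lp) else vol_work,
      opts$azimuth_step_deg, -tilt_max, tilt_max, tilt_step)
    asn <- match_segments(stk, refs, opts$psi_search_deg,
                          opts$psi_step_deg, opts$shift_search_px,
                          opts$shift_step_px,
                          mask_radius_px = mask_ang / apx)
    vol_new <- center_filament(back_project(stk, asn, apx, ramp = opts$ramp),
                               mask_ang, opts$z_frac)
    base_vol <- NULL
    if (opts$noise_baseline) {
      # deterministic azimuth scramble (golden-angle sequence): signal
      # decoheres, noise statistics are preserved
      asn_b <- asn
      asn_b$azimuth_deg <- (seq_len(nrow(asn)) * 222.4922 + cy * 77.7) %% 360
      base_vol <- back_project(stk, asn_b, apx, ramp = opts$ramp)
      if (hs_lp >= 2 * apx) base_vol <- lowpass(base_vol, hs_lp)
    }
    hs <- tryCatch(
      hsearch(if (hs_lp >= 2 * apx) lowpass(vol_new, hs_lp) else vol_new,
              sym$twist_deg + c(-1, 1) * opts$twist_window_deg,
              sym$rise_ang + c(-1, 1) * opts$rise_window_ang,
              opts$coarse_steps, opts$refine_tol, mask_ang, opts$z_frac,
              baseline_vol = base_vol, n_ops = opts$hsearch_n_ops),
      degenerate_search = function(e) {
        if (cyl_init && cy <= opts$hold_sym_cycles) NULL else stop(e)
      })
    if (!is.null(hs))
      sym <- helical_symmetry(hs$twist_deg, hs$rise_ang, sym$cn_order)
    vol_work <- impose_helical_symmetry(vol_new, sym, mask_ang,
                                        opts$z_frac)
    traj <- rbind(traj, data.frame(
      cycle = cy, twist_deg = sym$twist_deg, rise_ang = sym$rise_ang,
      residual = if (is.null(hs)) NA_real_ else hs$residual,
      mean_cc = mean(asn$cross_correlation)))
    if (verbose)
      message(sprintf("cycle %d: twist %.3f deg, rise %.3f A, cc %.3f",
                      cy, sym$twist_deg, sym$rise_ang,
                      mean(asn$cross_correlation)))
  }
  k <- nrow(traj)
  converged <- k >= 4 &&
    all(abs(diff(tail(traj$twist_deg, 4))) < 0.05) &&
    all(abs(diff(tail(traj$rise_ang, 4))) < 0.02)
  structure(list(trajectory = traj, sym = sym, volume = vol_work,
                 assignments = asn, opts = opts, cycles = cycles,
                 converged = converged, seed = seed, apix = apix_ang),
            class = "ihrsr")
}

#' @export
print.ihrsr <- function(x, ...) {
  cat(sprintf("IHRSR refinement, %d cycles%s\n", x$cycles,
              if (x$converged) " (converged)" else ""))
  print(x$sym)
  invisible(x)
}

#' @export
coef.ihrsr <- function(object, ...) {
  c(twist_deg = object$sym$twist_deg, rise_ang = object$sym$rise_ang)
}

#' @export
summary.ihrsr <- function(object, ...) {
  structure(list(sym = object$sym, trajectory = object$trajectory,
                 converged = object$converged,
                 mean_cc = tail(object$trajectory$mean_cc, 1)),
            class = "summary.ihrsr")
}

#' @export
print.summary.ihrsr <- function(x, ...) {
  cat("IHRSR refinement summary\n")
  print(x$sym)
  cat(sprintf("converged: %s, final mean correlation: %.4f\n",
              x$converged, x$mean_cc))
  cat("trajectory:\n")
  print(x$trajectory, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.ihrsr <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  tr <- x$trajectory
  graphics::plot(tr$cycle, tr$twist_deg, type = "b", xlab = "cycle",
                 ylab = "twist (deg)", ...)
  graphics::plot(tr$cycle, tr$rise_ang, type = "b", xlab = "cycle",
                 ylab = "rise (A)", ...)
  invisible(x)
}

#' @export
predict.ihrsr <- function(object, azimuth_deg = 0, tilt_deg = 0,
                          psi_deg = 0, ...) {
  project(object$volume, azimuth_deg, tilt_deg, psi_deg)
}

#' Center a filament on the box axis
#'
#' Estimates the in-plane center of mass of the (low-passed, positive)
#' density over the central axial band and shifts the volume so the
#' filament axis passes through the box center; helical symmetrization
#' about the box axis is only valid for a centered filament, so the
#' refinement loop recenters every cycle.
#'
#' @param vol a [volume_grid()].
#' @param mask_radius_ang radius of the region considered.
#' @param z_frac central axial fraction used for the estimate.
#' @param lowpass_ang smoothing applied to the copy used for the
#'   estimate (the returned volume is only shifted, not filtered).
#' @return centered [volume_grid()] with attribute `axis_shift_px`.
#' @export
center_filament <- function(vol, mask_radius_ang = NULL, z_frac = 0.6,
                            lowpass_ang = NULL) {
  n <- dim(vol)[1]
  apx <- apix(vol)
  if (is.null(mask_radius_ang)) mask_radius_ang <- n * apx / 3
  if (is.null(lowpass_ang)) lowpass_ang <- 4 * apx
  sm <- as_plain_array(lowpass(vol, lowpass_ang))
  ax <- seq_len(n) - 1 - floor(n / 2)
  in_mask <- outer(ax^2, ax^2, `+`) <= (mask_radius_ang / apx)^2
  band <- seq.int(ceiling((n - 1) * (0.5 - z_frac / 2)) + 1L,
                  floor((n - 1) * (0.5 + z_frac / 2)) + 1L)
  w <- pmax(sm[, , band], 0) * as.numeric(in_mask)
  dim(w) <- c(n, n, length(band))
  tot <- sum(w)
  if (tot <= 0) return(vol)
  comx <- sum(outer(ax, rep(1, n)) * rowSums(w, dims = 2)) / tot
  comy <- sum(outer(rep(1, n), ax) * rowSums(w, dims = 2)) / tot
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  px <- exp(-2i * pi * k * (-comx) / n)
  py <- exp(-2i * pi * k * (-comy) / n)
  ph <- outer(outer(px, py), rep(1 + 0i, n))
  out <- Re(fft(fft(as_plain_array(vol)) * ph, inverse = TRUE)) / n^3
  structure(volume_grid(array(out, rep(n, 3)), apx),
            axis_shift_px = c(-comx, -comy))
}
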