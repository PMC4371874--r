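#' Orientation grid for reference projections
#'
#' Azimuths step through `azimuth_range` (360 degrees, or `360/cn` when
#' exploiting point-group equivalence) and tilts span a symmetric range.
#' Ordering is tilt-major, azimuth-minor and deterministic.
#'
#' @param azimuth_step_deg azimuth increment; must divide `azimuth_range`.
#' @param tilt_min_deg,tilt_max_deg symmetric tilt range.
#' @param tilt_step_deg tilt increment.
#' @param azimuth_range_deg searched azimuth extent.
#' @return data.frame with `azimuth_deg`, `tilt_deg`.
#' @export
reference_grid <- function(azimuth_step_deg = 4, tilt_min_deg = -20,
                           tilt_max_deg = 20, tilt_step_deg = 4,
                           azimuth_range_deg = 360) {
  if (azimuth_range_deg %% azimuth_step_deg != 0)
    stop("azimuth_step_deg must divide the azimuth range")
  if (abs(tilt_min_deg + tilt_max_deg) > 1e-9)
    stop("tilt range must be symmetric about zero")
  tilts <- seq(tilt_min_deg, tilt_max_deg, by = tilt_step_deg)
  az <- seq(0, azimuth_range_deg - azimuth_step_deg, by = azimuth_step_deg)
  data.frame(azimuth_deg = rep(az, times = length(tilts)),
             tilt_deg = rep(tilts, each = length(az)))
}

#' Reference projection set over azimuth and out-of-plane tilt
#'
#' Projects a reference volume at every grid orientation (psi = 0, no
#' shift).  The default grid (4 degree azimuths, tilts -20..20 in 4 degree
#' steps) yields 90 x 11 = 990 references.
#'
#' @param volume reference [volume_grid()].
#' @inheritParams reference_grid
#' @return object of class `reference_set`: list with `projections`
#'   (n x n x R stack), `grid`, `apix`.
#' @export
make_reference_set <- function(volume, azimuth_step_deg = 4,
                               tilt_min_deg = -20, tilt_max_deg = 20,
                               tilt_step_deg = 4, azimuth_range_deg = 360) {
  grid <- reference_grid(azimuth_step_deg, tilt_min_deg, tilt_max_deg,
                         tilt_step_deg, azimuth_range_deg)
  n <- dim(volume)[1]
  proj <- array(0, c(n, n, nrow(grid)))
  for (i in seq_len(nrow(grid)))
    proj[, , i] <- project(volume, grid$azimuth_deg[i], grid$tilt_deg[i])
  attr(proj, "apix") <- apix(volume)
  structure(list(projections = proj, grid = grid, apix = apix(volume)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d projections, %d px @ %.3g A/px\n",
              nrow(x$grid), dim(x$projections)[1], x$apix))
  invisible(x)
}

# mask-weighted normalization: sqrt(w) * (x - wmean) / norm; returns a
# vector ready for plain dot-product correlation (or NULL if degenerate)
.ncc_normalize <- function(img, sqw, w, wsum) {
  mu <- sum(w * img) / wsum
  v <- sqw * (img - mu)
  nrm <- sqrt(sum(v * v))
  if (nrm < 1e-12) return(NULL)
  v / nrm
}

# normalized reference matrix (nref x npix)
.normalize_refs <- function(refs, mask) {
  n <- dim(refs$projections)[1]
  sqw <- sqrt(mask); wsum <- sum(mask)
  nref <- nrow(refs$grid)
  out <- matrix(0, nref, n * n)
  for (i in seq_len(nref)) {
    v <- .ncc_normalize(refs$projections[, , i], sqw, mask, wsum)
    if (is.null(v)) stop("degenerate (flat) reference projection ", i)
    out[i, ] <- v
  }
  out
}

#' Match segments against a reference set
#'
#' Exhaustive normalized cross-correlation over references x discretized
#' in-plane rotations x integer shifts, under a soft cylindrical filament
#' mask; the best-scoring assignment wins, ties broken deterministically in
#' favor of the lowest grid index.  The assigned (psi, sx, sy) is the
#' transform carrying the reference into the segment.
#'
#' @param segments 3-D stack (or a single [image_grid()] for
#'   `match_segment`).
#' @param refs a [make_reference_set()] result.
#' @param psi_search_deg,psi_step_deg in-plane search half-range and step.
#' @param shift_search_px,shift_step_px shift search half-range and step;
#'   fractional steps are supported (sub-pixel shifts are applied in
#'   Fourier space), which matters whenever the helical rise is close to
#'   the pixel size.
#' @param mask_radius_px soft mask radius (default box/3).
#' @param mask_v_frac axial fraction of the box included in the mask;
#'   restricting the comparison to the central band avoids a systematic
#'   preference for high-tilt references, whose projections fade toward
#'   the box ends.
#' @param refine_shifts after the discrete search, re-estimate the shift
#'   of the winning (reference, psi) pair continuously by FFT
#'   cross-correlation with parabolic sub-pixel interpolation.  Helical
#'   lattices make azimuth and axial shift nearly degenerate along the
#'   screw direction, and the compensating shift is a small fraction of a
#'   pixel per azimuth step, so sub-pixel shifts are essential for a
#'   phase-coherent reconstruction.
#' @return data.frame of assignments: `segment_id`, `azimuth_deg`,
#'   `tilt_deg`, `psi_deg`, `shift_x_px`, `shift_y_px`,
#'   `cross_correlation`, `flagged` (TRUE for zero-variance segments,
#'   which get correlation 0), `orientation = "assigned"`.
#' @export
match_segments <- function(segments, refs, psi_search_deg = 10,
                           psi_step_deg = 1, shift_search_px = 5,
                           shift_step_px = 1, mask_radius_px = NULL,
                           mask_v_frac = 0.7, refine_shifts = TRUE) {
  n <- dim(refs$projections)[1]
  stk <- if (length(dim(segments)) == 2L)
    array(as_plain_array(segments), c(n, n, 1)) else segments
  if (dim(stk)[1] != n || dim(stk)[2] != n)
    stop("segment and reference box sizes differ")
  if (is.null(mask_radius_px)) mask_radius_px <- n / 3
  mask <- filament_mask(n, mask_radius_px, v_frac = mask_v_frac)
  sqw <- sqrt(mask); wsum <- sum(mask)
  Rn <- .normalize_refs(refs, mask)
  psis <- seq(-psi_search_deg, psi_search_deg, by = psi_step_deg)
  shifts <- seq(-shift_search_px, shift_search_px, by = shift_step_px)
  vgrid <- expand.grid(sy = shifts, sx = shifts, psi = psis)[, 3:1]
  nv <- nrow(vgrid)
  m <- dim(stk)[3]
  out <- vector("list", m)
  for (si in seq_len(m)) {
    seg <- stk[, , si]
    if (sd(seg) < 1e-12) {
      g1 <- refs$grid[1, ]
      out[[si]] <- data.frame(segment_id = si, azimuth_deg = g1$azimuth_deg,
                              tilt_deg = g1$tilt_deg, psi_deg = 0,
                              shift_x_px = 0, shift_y_px = 0,
                              cross_correlation = 0, flagged = TRUE)
      next
    }
    V <- matrix(0, nv, n * n)
    vi <- 0L
    for (psi in psis) {
      rot <- if (psi == 0) seg else cpp_rotate2d(seg, -psi * pi / 180)
      for (sx in shifts) for (sy in shifts) {
        vi <- vi + 1L
        img <- if (sx == 0 && sy == 0) rot
        else if (sx == round(sx) && sy == round(sy))
          shift_image(rot, -sx, -sy)
        else fourier_shift(rot, -sx, -sy)
        v <- .ncc_normalize(img, sqw, mask, wsum)
        if (!is.null(v)) V[vi, ] <- v
      }
    }
    # note vgrid rows are in psi-major, sx, sy order to match the loop
    cc <- Rn %*% t(V)                 # nref x nv
    best <- which.max(cc)             # column-major: lowest ref index wins
    bi <- (best - 1L) %% nrow(cc) + 1L
    bj <- (best - 1L) %/% nrow(cc) + 1L
    sx <- vgrid$sx[bj]; sy <- vgrid$sy[bj]
    if (refine_shifts) {
      rot <- if (vgrid$psi[bj] == 0) seg
             else cpp_rotate2d(seg, -vgrid$psi[bj] * pi / 180)
      sh <- .refine_shift(rot * mask, refs$projections[, , bi] * mask,
                          shift_search_px + 1)
      if (!is.null(sh)) { sx <- sh[1]; sy <- sh[2] }
    }
    out[[si]] <- data.frame(
      segment_id = si,
      azimuth_deg = refs$grid$azimuth_deg[bi],
      tilt_deg = refs$grid$tilt_deg[bi],
      psi_deg = vgrid$psi[bj], shift_x_px = sx, shift_y_px = sy,
      cross_correlation = cc[best], flagged = FALSE)
  }
  res <- do.call(rbind, out)
  res$orientation <- "assigned"
  res
}

#' @rdname match_segments
#' @param segment a single [image_grid()].
#' @export
match_segment <- function(segment, refs, psi_search_deg = 10,
                          psi_step_deg = 1, shift_search_px = 5,
                          shift_step_px = 1, mask_radius_px = NULL,
                          mask_v_frac = 0.7, refine_shifts = TRUE) {
  match_segments(segment, refs, psi_search_deg, psi_step_deg,
                 shift_search_px, shift_step_px, mask_radius_px,
                 mask_v_frac, refine_shifts)
}

# continuous shift estimate: FFT cross-correlation peak (restricted to
# |shift| <= search) with 3-point parabolic sub-pixel interpolation;
# `a` plays the segment, `b` the reference: returns s with a ~ shift(b, s)
.refine_shift <- function(a, b, search) {
  n <- nrow(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / n^2
  cc <- fftshift(cc)
  cen <- floor(n / 2) + 1L
  win <- max(1L, round(search))
  idx <- (cen - win):(cen + win)
  sub <- cc[idx, idx]
  p <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  ti <- idx[p[1]]; tj <- idx[p[2]]
  para <- function(m1, m0, p1) {
    d <- m1 - 2 * m0 + p1
    if (d >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / d))
  }
  dx <- if (ti > 1 && ti < n) para(cc[ti - 1, tj], cc[ti, tj], cc[ti + 1, tj]) else 0
  dy <- if (tj > 1 && tj < n) para(cc[ti, tj - 1], cc[ti, tj], cc[ti, tj + 1]) else 0
  c(ti - cen + dx, tj - cen + dy)
}

#' Histogram of assigned out-of-plane tilts
#'
#' Counts per reference tilt value; bin centers are symmetric about zero
#' with spacing `tilt_step_deg` and counts sum to the number of segments.
#'
#' @param assignments output of [match_segments()].
#' @param tilt_step_deg bin spacing (the reference tilt step).
#' @return data.frame of class `tilt_histogram`: `tilt_deg`, `count`.
#' @export
tilt_histogram <- function(assignments, tilt_step_deg = 4) {
  tmax <- max(abs(assignments$tilt_deg))
  centers <- seq(-tmax, tmax, by = tilt_step_deg)
  counts <- vapply(centers, function(b)
    sum(abs(assignments$tilt_deg - b) < tilt_step_deg / 2), integer(1))
  structure(data.frame(tilt_deg = centers, count = counts),
            class = c("tilt_histogram", "data.frame"))
}

#' @export
plot.tilt_histogram <- function(x, ...) {
  graphics::barplot(x$count, names.arg = x$tilt_deg,
                    xlab = "out-of-plane tilt (deg)", ylab = "segments",
                    ...)
  invisible(x)
}

#' Select segments assigned to the central (low-tilt) bins
#'
#' @param assignments output of [match_segments()].
#' @param central_bins tilt values to keep (degrees).
#' @return the matching rows, order preserved (empty with a warning when
#'   nothing matches).
#' @export
select_low_tilt <- function(assignments, central_bins = c(-4, 0, 4)) {
  keep <- assignments$tilt_deg %in% central_bins
  if (!any(keep)) warning("no segments in the requested tilt bins")
  assignments[keep, , drop = FALSE]
}
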