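test_that("FSC is 1 for identical maps, symmetric, and null for noise", {
  v <- vol48()
  cv <- fsc(v, v)
  expect_true(all(abs(cv$fsc - 1) < 1e-10))

  set.seed(3)
  a <- volume_grid(array(rnorm(32^3), rep(32, 3)), 4.6)
  b <- volume_grid(array(rnorm(32^3), rep(32, 3)), 4.6)
  ab <- fsc(a, b); ba <- fsc(b, a)
  expect_equal(ab$fsc, ba$fsc, tolerance = 1e-12)
  frac_null <- mean(abs(ab$fsc) < 3 / sqrt(ab$n_voxels))
  expect_gt(frac_null, 0.9)

  small <- volume_grid(array(0, rep(16, 3)), 4.6)
  expect_error(fsc(v, small), "identical grid")
})

test_that("threshold resolution interpolates and honors the sentinel", {
  curve <- structure(data.frame(freq = (1:10) / 100,
                                fsc = c(1, 1, 0.9, 0.8, 0.6, 0.4, 0.2,
                                        0.1, 0, 0),
                                n_voxels = rep(100, 10)),
                     class = c("fsc_curve", "data.frame"))
  r <- resolution_at(curve, 0.5)
  # crossing between shells 5 and 6: freq = 0.05 + 0.5 * 0.01
  expect_equal(r, 1 / 0.055, tolerance = 1e-10)

  const <- curve; const$fsc <- rep(1, 10)
  expect_true(is.na(resolution_at(const)))
  low <- curve; low$fsc[1] <- 0.3
  expect_error(resolution_at(low), "threshold")

  # an isolated dip below threshold is skipped
  dip <- curve; dip$fsc <- c(1, 1, 0.1, 0.9, 0.9, 0.4, 0.2, 0.1, 0, 0)
  expect_equal(resolution_at(dip), 1 / (0.05 + 0.8 * 0.01),
               tolerance = 1e-6)
})

test_that("a band-limited noisy pair crosses near its band limit", {
  set.seed(12)
  v <- vol48()
  noise <- function() array(rnorm(48^3, 0, 0.1 * sd(as.numeric(v))),
                            rep(48, 3))
  a <- lowpass(volume_grid(unclass(v) + noise(), 4.6), 15)
  b <- lowpass(volume_grid(unclass(v) + noise(), 4.6), 15)
  r <- resolution_at(fsc(a, b))
  expect_gt(r, 13); expect_lt(r, 22)
})

test_that("half-set reconstructions improve with segment count", {
  v <- vol48()
  set.seed(13)
  m <- 120
  az <- runif(m, 0, 360)
  stk <- array(0, c(48, 48, m))
  for (i in seq_len(m))
    stk[, , i] <- unclass(project(v, az[i], 0)) + rnorm(48^2, 0, 0.004)
  attr(stk, "apix") <- 4.6
  asn <- data.frame(azimuth_deg = az, tilt_deg = 0, psi_deg = 0,
                    shift_x_px = 0, shift_y_px = 0)
  half_res <- function(idx) {
    ev <- idx[idx %% 2 == 0]; od <- idx[idx %% 2 == 1]
    a <- back_project(stk[, , ev, drop = FALSE], asn[ev, ], 4.6)
    b <- back_project(stk[, , od, drop = FALSE], asn[od, ], 4.6)
    resolution_at(fsc(a, b))
  }
  r_small <- half_res(1:30)
  r_big <- half_res(1:120)
  expect_true(is.na(r_big) || is.na(r_small) || r_big <= r_small + 1)
})

test_that("B-factor weighting cancels and the default pipeline runs", {
  set.seed(14)
  v <- volume_grid(array(rnorm(32^3), rep(32, 3)), 2.3)
  sharp <- amplitude_correct(v, list(), bfactor = -300, lowpass_ang = NULL)
  back <- amplitude_correct(sharp, list(), bfactor = 300,
                            lowpass_ang = NULL)
  expect_lt(max(abs(back - v)) / max(abs(v)), 1e-6)

  ctfs <- list(ctf_params(2.0), ctf_params(3.5))
  out <- amplitude_correct(vol48(), ctfs)
  expect_s3_class(out, "volume_grid")

  # bfactor 0, no CTFs: pure low-pass
  lp <- amplitude_correct(v, list(), bfactor = 0, lowpass_ang = 9.2)
  expect_equal(as.numeric(lp), as.numeric(lowpass(v, 9.2)),
               tolerance = 1e-10)
})

test_that("the low-pass removes essentially all power beyond the cutoff", {
  set.seed(15)
  v <- volume_grid(array(rnorm(32^3), rep(32, 3)), 2.3)
  out <- lowpass(v, 10)
  f <- helixamb:::vol_freq_grid(32, 2.3)
  p_in <- Mod(fft(unclass(v)))^2
  p_out <- Mod(fft(unclass(out)))^2
  hi <- f > 1 / 10
  expect_lt(sum(p_out[hi]) / sum(p_in[hi]), 0.01)
  expect_error(lowpass(v, 3), "Nyquist")
})

test_that("model rasterization conserves mass and position", {
  one <- data.frame(x = 0, y = 0, z = 0, weight = 2)
  v <- model_to_map(one, 2.3, 32, 10)
  expect_equal(sum(v), 2, tolerance = 1e-6)
  ax <- (seq_len(32) - 1 - 16) * 2.3
  w <- pmax(unclass(v), 0)
  com <- c(sum(w * ax[slice.index(w, 1)]), sum(w * ax[slice.index(w, 2)]),
           sum(w * ax[slice.index(w, 3)])) / sum(w)
  expect_lt(max(abs(com)), 0.23)

  many <- data.frame(x = c(-10, 5), y = c(0, 8), z = c(4, -6),
                     weight = c(1, 3))
  expect_equal(sum(model_to_map(many, 2.3, 32, 10)), 4, tolerance = 1e-6)
  far <- data.frame(x = 500, y = 0, z = 0, weight = 1)
  expect_error(model_to_map(far, 2.3, 32, 10), "outside")
})

test_that("a rasterized helical model reproduces its layer lines", {
  ops <- symmetry_operators(c1_sym(), -20, 20)
  ang <- ops$rotation_deg * pi / 180
  pts <- data.frame(x = 30 * cos(ang), y = 30 * sin(ang),
                    z = ops$translation_ang, weight = 1)
  v <- model_to_map(pts, 2.3, 96, 10)
  z1 <- 1 / one_start_pitch(c1_sym())
  pr <- layer_line_profile(power_spectrum(project(v, 13, 0)), z1, 2)
  expect_equal(meridional_classification(pr)$class, "off_meridian")
})

test_that("cylindrical averages are rotation invariant and expose the hole", {
  # exact rotation oracle: rebuild the same filament with the subunit
  # rotated 37 degrees about the axis, so only the averaging itself can
  # differ
  a <- 37 * pi / 180
  rotsub <- blob_model(matrix(c(30 * cos(a), 30 * sin(a), 0), 1),
                       sigma_ang = 8)
  v <- lowpass(vol96(), 12)
  vr <- lowpass(build_filament_volume(c1_sym(), rotsub, 96, 2.3), 12)
  p0 <- cylindrical_average(v)
  p1 <- cylindrical_average(vr)
  # the z-averaged radial profile is rotation invariant to < 1 percent;
  # individual (r, z) bins carry a few percent of annular sampling noise
  expect_lt(sqrt(mean((rowMeans(p0) - rowMeans(p1))^2)) /
              sqrt(mean(rowMeans(p0)^2)), 0.01)
  expect_lt(sqrt(mean((p0 - p1)^2)) / sqrt(mean(p0^2)), 0.05)

  expect_lt(axial_hole_metric(p0), 0.5)

  cyl <- helixamb:::solid_cylinder(48, 2.3, 40)
  expect_gt(axial_hole_metric(cylindrical_average(cyl)), 0.8)

  # hollow tube scores near zero
  tube <- unclass(helixamb:::solid_cylinder(48, 2.3, 45)) -
    unclass(helixamb:::solid_cylinder(48, 2.3, 30))
  expect_lt(axial_hole_metric(cylindrical_average(
    volume_grid(tube, 2.3))), 0.1)
})

test_that("helical gauge alignment recovers a known transform", {
  v <- impose_helical_symmetry(vol48(), c1_sym(), 45)
  moved <- volume_grid(array(helixamb:::cpp_zrot_shift(
    as.numeric(v), 48, 25 * pi / 180, 1.2), rep(48, 3)), 4.6)
  ali <- align_helical_volume(moved, v, 45)
  expect_gt(attr(ali, "correlation"), 0.97)
  r <- resolution_at(fsc(ali, v))
  expect_true(is.na(r) || r < 20)
})
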