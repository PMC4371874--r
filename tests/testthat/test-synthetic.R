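test_that("filament volumes rasterize the symmetry-transformed subunit", {
  # an on-axis blob gives a cylindrically symmetric rod
  rod <- build_filament_volume(c1_sym(), blob_model(c(0, 0, 0), 8),
                               32, 4.6)
  prof <- cylindrical_average(rod)
  rot <- volume_grid(array(helixamb:::cpp_zrot_shift(as.numeric(rod), 32,
                                                     0.9, 0), rep(32, 3)),
                     4.6)
  expect_gt(cor(as.numeric(rot), as.numeric(rod)), 0.999)
  expect_gt(prof[1, 16], max(prof[10:16, 16]))

  # total mass tracks subunit count x weight
  v1 <- build_filament_volume(c1_sym(), default_subunit(), 48, 4.6,
                              n_subunits = 11)
  v2 <- build_filament_volume(c1_sym(), default_subunit(), 48, 4.6,
                              n_subunits = 22)
  expect_equal(sum(v2) / sum(v1), 2, tolerance = 1e-3)

  expect_error(build_filament_volume(c1_sym(), default_subunit(), 32, 2.3,
                                     n_subunits = 40), "overflow")
})

test_that("projection conserves density and is linear", {
  v <- vol48()
  p <- project(v, 33, 0, 0)
  expect_equal(sum(p), sum(v) * apix(v), tolerance = 1e-3)
  # linearity
  v2 <- volume_grid(array(2 * as.numeric(v), dim(v)), apix(v))
  p2 <- project(v2, 33, 0, 0)
  expect_equal(as.numeric(p2), 2 * as.numeric(p), tolerance = 1e-10)
})

test_that("tilt collapses the off-meridional layer-line pair", {
  v <- vol96()
  z1 <- 1 / one_start_pitch(c1_sym())
  p0 <- power_spectrum(project(v, 21, 0))
  cl0 <- meridional_classification(layer_line_profile(p0, z1, 2))
  expect_equal(cl0$class, "off_meridian")
  p12 <- power_spectrum(project(v, 21, 12))
  cl12 <- meridional_classification(layer_line_profile(p12, z1, 2))
  expect_equal(cl12$class, "on_meridian")
})

test_that("the CTF has the stated low-frequency and zero structure", {
  p <- ctf_params(defocus_um = 3.2, cs_mm = 2.0, kv = 300,
                  amp_contrast = 0.07)
  expect_equal(ctf_evaluate(p, 0), -0.07)
  expect_equal(ctf_evaluate(ctf_params(amp_contrast = 1), 0), -1)
  expect_equal(electron_wavelength(300), 0.0197, tolerance = 1e-3)

  # first zero against an independent bracketed root find on the
  # full transfer function
  f0 <- uniroot(function(f) ctf_evaluate(p, f), c(0.001, 0.05),
                tol = 1e-10)$root
  expect_equal(ctf_evaluate(p, f0), 0, tolerance = 1e-8)
  expect_lt(ctf_evaluate(p, f0 - 0.002) * ctf_evaluate(p, f0 + 0.002), 0)
})

test_that("CTF application keeps images real and composes as expected", {
  set.seed(5)
  img <- image_grid(matrix(rnorm(48^2), 48, 48), 2.3)
  p <- ctf_params(defocus_um = 2.5, apix_ang = 2.3)
  once <- apply_ctf(img, p, "multiply")
  twice <- apply_ctf(once, p, "multiply")
  # multiplying twice equals weighting the FT by CTF^2
  h <- ctf_evaluate(p, helixamb:::ctf_freq_grid(48, 2.3))
  direct <- Re(fft(fft(unclass(img)) * h^2, inverse = TRUE)) / 48^2
  expect_equal(as.numeric(twice), as.numeric(direct), tolerance = 1e-10)

  # phase flipping twice restores the original image
  flip2 <- apply_ctf(apply_ctf(img, p, "phase_flip"), p, "phase_flip")
  expect_equal(as.numeric(flip2), as.numeric(img), tolerance = 1e-10)
})

test_that("segment extraction arithmetic matches the overlap design", {
  expect_equal(extract_segments(192, 192, 6), 0L)
  expect_equal(extract_segments(204, 192, 6), c(0L, 6L, 12L))
  expect_equal(length(extract_segments(192 + 99 * 6, 192, 6)), 100L)
  expect_equal(segment_overlap(192, 6), 0.96875)
  expect_equal(round(100 * segment_overlap(192, 6)), 97)
  expect_warning(out <- extract_segments(100, 192, 6), "shorter")
  expect_length(out, 0)
})

test_that("simulated datasets are reproducible and obey their draws", {
  s1 <- simulate_dataset(c1_sym(), n_filaments = 4,
                         segments_per_filament = 3, box_px = 48,
                         apix_ang = 4.6, snr = 0.5, seed = 123)
  s2 <- simulate_dataset(c1_sym(), n_filaments = 4,
                         segments_per_filament = 3, box_px = 48,
                         apix_ang = 4.6, snr = 0.5, seed = 123)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(c1_sym(), n_filaments = 4,
                         segments_per_filament = 3, box_px = 48,
                         apix_ang = 4.6, snr = 0.5, seed = 124)
  expect_false(identical(s1$stack, s3$stack))
  expect_error(simulate_dataset(c1_sym(), snr = -1, seed = 1), "snr")
  expect_error(simulate_dataset(c1_sym(), tilt_max_deg = -3, seed = 1),
               "tilt")
})

test_that("tilt and defocus draws match their truncated normals", {
  big <- simulate_dataset(c1_sym(), n_filaments = 400,
                          segments_per_filament = 1, box_px = 32,
                          apix_ang = 4.6, snr = 1,
                          tilt_sigma_deg = 12, tilt_max_deg = 35,
                          seed = 99)
  tilts <- big$truth$tilt_deg
  expect_true(all(abs(tilts) <= 35))
  # tail probability of |t| > 20 for a truncated normal(0, 12, +-35)
  p_tail <- (2 * (pnorm(35, 0, 12) - pnorm(20, 0, 12))) /
    (2 * pnorm(35, 0, 12) - 1)
  expect_lt(abs(mean(abs(tilts) > 20) - p_tail),
            3 * sqrt(p_tail * (1 - p_tail) / 400))

  dfc <- big$truth$defocus_um
  expect_true(all(dfc >= 1.7 & dfc <= 5.4))
  expect_equal(mean(dfc), 3.2, tolerance = 0.15)
})

test_that("the noise level calibrates to the requested SNR", {
  clean <- simulate_dataset(c1_sym(), n_filaments = 6,
                            segments_per_filament = 1, box_px = 48,
                            apix_ang = 4.6, snr = 1e6, jitter_px = 0,
                            seed = 31)
  noisy <- simulate_dataset(c1_sym(), n_filaments = 6,
                            segments_per_filament = 1, box_px = 48,
                            apix_ang = 4.6, snr = 0.5, jitter_px = 0,
                            seed = 31)
  # same seed stream => same orientations; difference is the noise
  nse <- noisy$stack - clean$stack
  mask <- helixamb:::filament_mask(48, (30 + 16) / 4.6)
  snr_hat <- vapply(seq_len(dim(nse)[3]), function(i) {
    sig <- clean$stack[, , i]
    mu <- sum(mask * sig) / sum(mask)
    (sum(mask * (sig - mu)^2) / sum(mask)) / var(as.numeric(nse[, , i]))
  }, numeric(1))
  expect_equal(median(snr_hat), 0.5, tolerance = 0.1)
})
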