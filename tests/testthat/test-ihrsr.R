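test_that("symmetry imposition is near idempotent", {
  # a random smooth volume changes drastically on the first pass and by
  # only the trilinear-resampling floor on the second
  set.seed(2)
  rv <- lowpass(volume_grid(array(rnorm(48^3), rep(48, 3)), 4.6), 20)
  s1 <- impose_helical_symmetry(rv, c1_sym(), 50)
  s2 <- impose_helical_symmetry(s1, c1_sym(), 50)
  change1 <- sqrt(mean((s1 - rv)^2))
  change2 <- sqrt(mean((s2 - s1)^2))
  expect_lt(change2, 0.15 * change1)  # trilinear floor ~7 percent

  # an already-symmetric volume barely changes inside the band where
  # sources live (imposition extends the lattice into the box margins,
  # where the finite filament of the input has ended)
  v <- vol48()
  sv <- impose_helical_symmetry(v, c1_sym(), 50)
  ax <- seq_len(48) - 1 - 24
  in_mask <- outer(ax^2, ax^2, `+`) <= (50 / 4.6)^2
  band <- 11:38
  sel <- rep(in_mask, length(band))
  expect_gt(cor(unclass(sv)[, , band][sel], unclass(v)[, , band][sel]),
            0.98)

  expect_error(impose_helical_symmetry(v, c1_sym(), 500), "mask")
  expect_error(impose_helical_symmetry(v, helical_symmetry(-90, 60), 50),
               "band")
})

test_that("imposition drives the helical residual far down", {
  set.seed(2)
  rv <- volume_grid(array(rnorm(48^3), rep(48, 3)), 4.6)
  rv <- lowpass(rv, 20)
  res <- function(v) helixamb:::cpp_helical_residual(
    as.numeric(v), 48, -101.1 * pi / 180, 5.1 / 4.6, 50 / 4.6,
    47 * 0.2, 47 * 0.8)[1]
  pre <- res(rv)
  post <- res(impose_helical_symmetry(rv, c1_sym(), 50))
  expect_lt(post, 0.05 * pre)
})

test_that("hsearch recovers clean symmetry and rejects featureless input", {
  hs <- hsearch(vol48(), c(-106, -96), c(4.1, 6.1))
  expect_lt(abs(hs$twist_deg + 101.1), 0.1)
  expect_lt(abs(hs$rise_ang - 5.1), 0.05)
  expect_true(is.matrix(hs$surface))

  cyl <- helixamb:::solid_cylinder(48, 4.6, 40)
  expect_error(hsearch(cyl, c(-106, -96), c(4.1, 6.1)), "degenerate")
  expect_error(hsearch(vol48(), c(-96, -106), c(4.1, 6.1)),
               "non-degenerate")
})

test_that("hsearch is invariant under axial translation of the volume", {
  v <- impose_helical_symmetry(vol48(), c1_sym(), 50)
  shifted <- volume_grid(array(helixamb:::cpp_zrot_shift(
    as.numeric(v), 48, 0, 2.0), rep(48, 3)), 4.6)
  h0 <- hsearch(v, c(-103, -99), c(4.7, 5.5))
  h1 <- hsearch(shifted, c(-103, -99), c(4.7, 5.5))
  expect_lt(abs(h0$twist_deg - h1$twist_deg), 0.15)
  expect_lt(abs(h0$rise_ang - h1$rise_ang), 0.08)
})

test_that("multi-operator chaining sharpens the symmetry search", {
  v <- vol48()
  h1 <- hsearch(v, c(-103, -99), c(4.7, 5.5), n_ops = 6)
  expect_lt(abs(h1$twist_deg + 101.1), 0.1)
  expect_lt(abs(h1$rise_ang - 5.1), 0.05)
})

test_that("decimation crops the Fourier transform and keeps the mean", {
  v <- vol48()
  expect_identical(decimate(v, 1), v)
  d <- decimate(v, 2)
  expect_equal(dim(d), rep(24L, 3))
  expect_equal(apix(d), 9.2)
  expect_equal(mean(d), mean(v), tolerance = 1e-10)
  expect_error(decimate(v, 5), "divide")

  img <- project(v, 0, 0)
  di <- decimate(img, 2)
  expect_equal(dim(di), c(24L, 24L))
  expect_equal(mean(di), mean(img), tolerance = 1e-10)
})

test_that("back-projection reproduces a volume from its projections", {
  v <- vol48()
  az <- seq(0, 352, 8)
  stk <- array(0, c(48, 48, length(az)))
  for (i in seq_along(az)) stk[, , i] <- project(v, az[i], 0)
  attr(stk, "apix") <- 4.6
  asn <- data.frame(azimuth_deg = az, tilt_deg = 0, psi_deg = 0,
                    shift_x_px = 0, shift_y_px = 0)
  rec <- back_project(stk, asn, 4.6)
  cv <- fsc(rec, v)
  # well correlated through the low and mid shells
  expect_gt(min(cv$fsc[1:8]), 0.8)

  single <- back_project(stk[, , 1, drop = FALSE],
                         asn[1, , drop = FALSE], 4.6)
  expect_s3_class(single, "volume_grid")
  expect_gt(sum(abs(single)), 0)
  expect_error(back_project(stk, asn[1:3, ], 4.6), "match")
})

test_that("tilted segments reconstruct better when tilt is honored", {
  v <- vol48()
  grid <- expand.grid(azimuth_deg = seq(0, 345, 15), tilt_deg = c(-12, 12))
  stk <- array(0, c(48, 48, nrow(grid)))
  for (i in seq_len(nrow(grid)))
    stk[, , i] <- project(v, grid$azimuth_deg[i], grid$tilt_deg[i])
  attr(stk, "apix") <- 4.6
  asn_t <- data.frame(grid, psi_deg = 0, shift_x_px = 0, shift_y_px = 0)
  asn_0 <- asn_t; asn_0$tilt_deg <- 0
  rec_t <- back_project(stk, asn_t, 4.6)
  rec_0 <- back_project(stk, asn_0, 4.6)
  f_t <- fsc(rec_t, v); f_0 <- fsc(rec_0, v)
  expect_gt(mean(f_t$fsc[3:12]), mean(f_0$fsc[3:12]))
})

test_that("the refinement loop is reproducible and holds a true start", {
  v <- vol48()
  set.seed(4)
  m <- 60
  az <- runif(m, 0, 360)
  stk <- array(0, c(48, 48, m))
  for (i in seq_len(m)) stk[, , i] <- project(v, az[i], 0)
  attr(stk, "apix") <- 4.6
  opts <- ihrsr_options(azimuth_step_deg = 8, mask_radius_ang = 50,
                        init_volume = v, psi_search_deg = 2,
                        shift_search_px = 1, noise_baseline = FALSE)
  fit <- ihrsr(stk, c1_sym(), cycles = 2, opts = opts, seed = 1)
  expect_s3_class(fit, "ihrsr")
  expect_equal(nrow(fit$trajectory), 3L)
  expect_lt(abs(coef(fit)[["twist_deg"]] + 101.1), 0.5)
  expect_lt(abs(coef(fit)[["rise_ang"]] - 5.1), 0.2)

  fit2 <- ihrsr(stk, c1_sym(), cycles = 2, opts = opts, seed = 1)
  expect_identical(fit$trajectory, fit2$trajectory)
  expect_identical(as.numeric(fit$volume), as.numeric(fit2$volume))

  # methods
  expect_output(print(fit), "IHRSR")
  expect_output(print(summary(fit)), "trajectory")
  expect_equal(names(coef(fit)), c("twist_deg", "rise_ang"))
  pred <- predict(fit, azimuth_deg = 30)
  expect_s3_class(pred, "image_grid")
})

test_that("an offset start is pulled toward the true symmetry", {
  v <- vol48()
  set.seed(6)
  m <- 60
  az <- runif(m, 0, 360)
  stk <- array(0, c(48, 48, m))
  for (i in seq_len(m)) stk[, , i] <- project(v, az[i], 0)
  attr(stk, "apix") <- 4.6
  opts <- ihrsr_options(azimuth_step_deg = 8, mask_radius_ang = 50,
                        init_volume = v, psi_search_deg = 2,
                        shift_search_px = 1, noise_baseline = FALSE)
  fit <- ihrsr(stk, helical_symmetry(-99.5, 5.45), cycles = 3,
               opts = opts, seed = 1)
  expect_lt(abs(coef(fit)[["twist_deg"]] + 101.1), 0.6)
  expect_lt(abs(coef(fit)[["rise_ang"]] - 5.1), 0.2)
})

test_that("a solid-cylinder start tolerates early degenerate searches", {
  v <- vol48()
  set.seed(8)
  m <- 40
  az <- runif(m, 0, 360)
  stk <- array(0, c(48, 48, m))
  for (i in seq_len(m)) stk[, , i] <- project(v, az[i], 0)
  attr(stk, "apix") <- 4.6
  opts <- ihrsr_options(azimuth_step_deg = 12, mask_radius_ang = 50,
                        cylinder_radius_ang = 38, psi_search_deg = 2,
                        shift_search_px = 1, noise_baseline = FALSE,
                        hold_sym_cycles = 2)
  fit <- ihrsr(stk, c1_sym(), cycles = 2, opts = opts, seed = 1)
  expect_equal(nrow(fit$trajectory), 3L)
  # held or searched, the symmetry must remain plausible
  expect_lt(abs(coef(fit)[["twist_deg"]] + 101.1), 2.1)
})

test_that("filament centering restores an off-axis helix", {
  v <- impose_helical_symmetry(vol48(), c1_sym(), 40)
  off <- array(0, rep(48, 3))
  # shift the volume 2 voxels off axis in x by integer roll
  off[3:48, , ] <- unclass(v)[1:46, , ]
  off <- volume_grid(off, 4.6)
  cen <- center_filament(off, 60)
  shift <- attr(cen, "axis_shift_px")
  expect_equal(shift[1], -2, tolerance = 0.3)
  expect_lt(abs(shift[2]), 0.3)
})

test_that("early cycles can run on decimated images", {
  v <- build_filament_volume(c1_sym(), default_subunit(), 48, 2.3)
  set.seed(9)
  m <- 40
  az <- runif(m, 0, 360)
  stk <- array(0, c(48, 48, m))
  for (i in seq_len(m)) stk[, , i] <- project(v, az[i], 0)
  attr(stk, "apix") <- 2.3
  opts <- ihrsr_options(azimuth_step_deg = 12, mask_radius_ang = 48,
                        init_volume = v, psi_search_deg = 2,
                        shift_search_px = 1, noise_baseline = FALSE,
                        decimate_factor = 2, decimated_cycles = 1)
  fit <- ihrsr(stk, c1_sym(), cycles = 2, opts = opts, seed = 1)
  expect_equal(nrow(fit$trajectory), 3L)
  # after the decimated cycle the loop returns to the full sampling
  expect_equal(dim(fit$volume)[1], 48L)
  expect_equal(apix(fit$volume), 2.3)
  expect_lt(abs(coef(fit)[["twist_deg"]] + 101.1), 1)
})
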