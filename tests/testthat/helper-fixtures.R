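# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

c1_sym <- function() helical_symmetry(-101.1, 5.1)
c3_sym <- function() helical_symmetry(-53.6, 16.8, cn_order = 3L)

# small clean filament volume, 48 px at 4.6 A/px
vol48 <- function() fixture("vol48", function()
  build_filament_volume(c1_sym(), default_subunit(), 48, 4.6))

# clean filament volume at the acquisition sampling, 96 px at 2.3 A/px
vol96 <- function() fixture("vol96", function()
  build_filament_volume(c1_sym(), default_subunit(), 96, 2.3))

# tiny reference set over a coarse grid (box 48)
refs48 <- function() fixture("refs48", function()
  make_reference_set(vol48(), azimuth_step_deg = 30,
                     tilt_min_deg = -16, tilt_max_deg = 16,
                     tilt_step_deg = 8))

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
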