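---
title: "Diagnosing helical-symmetry ambiguities in filament reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing helical-symmetry ambiguities in filament reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(helixamb)
```

## The problem

A helical filament is a one-dimensional crystal: identical subunits
related by a rotation `twist` (degrees, negative for a left-handed
lattice) and a translation `rise` (Angstrom) about and along a common
axis, optionally combined with an n-fold point group `Cn`.  Because a
single projection of a filament shows many symmetry-related views, a
three-dimensional map can be computed from remarkably few images — but
the same property is a trap.  At limited resolution, several different
(twist, rise, Cn) lattices predict layer lines at indistinguishable
positions, and iterative refinement under a wrong symmetry can converge
and remain perfectly stable.  Stability is necessary, not sufficient.

This package implements the full diagnostic chain for studying that
failure mode on synthetic data:

* closed-form lattice mathematics — operators, layer-line prediction
  through the helical selection rule `z = (n * twist/360 + m)/rise`
  (Bessel order `n` restricted to multiples of Cn), the pitch of the
  1-start helix, and the out-of-plane tilt at which an off-meridional
  layer-line peak collapses onto the meridian;
* a synthetic cryo-EM generator (tilted projections of Gaussian-blob
  filaments, CTF modulation, calibrated noise);
* power-spectrum diagnostics (averaged spectra, layer-line profiles,
  meridional classification, central sections of 3-D spectra);
* reference-projection matching over azimuth and out-of-plane tilt with
  tilt histograms and low-tilt subset selection;
* the iterative helical real-space reconstruction (IHRSR) loop itself,
  exposed as the fitting function `ihrsr()`;
* validation: Fourier shell correlation (FSC), model rasterization,
  amplitude correction and cylindrical averaging.

## The tilt-collapse geometry

The power spectrum of a projection is a central section of the
three-dimensional power spectrum.  An off-meridional layer line of
Bessel order `n != 0` at axial frequency `z` peaks at radial frequency
`R = x1(|n|) / (2 pi r)`, where `x1` is the first maximum of `|J_n|`
(`x1(1) = 1.8412`) and `r` the helical radius of the subunit.  When the
filament axis tilts out of the projection plane by

```
tau = atan(R / z)
```

that peak lands on the meridian and mimics an `n = 0` line.  For the
1-start line at ~1/(18 A) and a subunit radius of about 33.5 A this is
~9 degrees — well inside the tilt range of filaments suspended in ice.
The subunit radius is an explicit argument of `collapse_tilt()`: it is
not derivable from the layer-line position alone, and the package makes
that dependence visible rather than assuming a value.

## The synthetic generator: what it emulates, and what it does not

`simulate_dataset()` reproduces the imaging conditions that make the
ambiguity dangerous:

* out-of-plane tilt drawn from a truncated normal (default sigma 12
  degrees, truncated at +-35) — filaments lie near a plane but far from
  perfectly;
* defocus drawn from a truncated normal with mean 3.2 um spanning
  1.7–5.4 um; images are formed by multiplying the ideal projection's
  Fourier transform by the CTF (underfocus positive, `CTF(0) = -A`,
  default 300 kV / Cs 2 mm / 7 percent amplitude contrast);
* 2.3 A/px sampling and 192-px overlapping windows stepped by 6 px
  (97 percent overlap) as the reference acquisition geometry; a window
  step of `t` Angstrom advances the view by `round(t/rise)` subunit
  twists plus a sub-rise axial shift, exactly as for an ideal helix;
* additive white Gaussian noise calibrated so the variance ratio
  between the CTF-modulated signal (inside the filament mask) and the
  noise equals `snr`; an optional low-frequency-boosted background
  field mimics a carbon-film support, with no claimed quantitative
  fidelity.

What it does not emulate: whole micrographs and particle picking,
beam-induced motion, amplitude falloff beyond the CTF envelope, and —
most importantly — protein-shaped subunits.  The default subunit is a
single Gaussian blob at a 30 A helical radius (blob width 8 A), which
reproduces the layer-line physics faithfully but is azimuthally
featureless; segments of one filament share tilt, in-plane rotation and
defocus.  Passing tests therefore demonstrate the behavior of the
algorithms under controlled helical geometry and noise, not performance
on real micrographs.

## The IHRSR loop and its numerical choices

`ihrsr()` alternates: project references from the current symmetrized
volume (azimuth grid, optionally an out-of-plane tilt grid), assign
every segment by masked normalized cross-correlation over discretized
in-plane rotations and shifts, back-project, search the helical
symmetry of the new reconstruction in a window around the current
estimate, impose it, repeat.  Per-cycle (twist, rise) values form the
trajectory that `plot()` displays; `coef()` returns the final pair.
Several numerical choices deserve explanation, because each one was
forced by a concrete failure mode of the naive implementation:

* **Sub-pixel shift refinement.**  Azimuth and axial shift are nearly
  degenerate along the screw direction: an azimuth error of one grid
  step is compensated by an axial shift of `step * rise / twist` —
  about 0.1 px for the default grids.  With shifts quantized at whole
  pixels the rise-scale lattice phase decoheres entirely (the pixel
  size aliases against the rise).  After the discrete search, the shift
  of the winning reference is therefore re-estimated continuously by
  FFT cross-correlation with parabolic interpolation.
* **Axially banded matching mask.**  Reference projections at large
  out-of-plane tilt fade toward the box ends (the tilted filament
  leaves the cube).  Compared under a full-length mask they attract
  noisy segments systematically; the mask is restricted to the central
  70 percent of the axial extent.
* **Spectrally matched references.**  Segments corrected by CTF
  multiplication carry CTF-squared amplitude weights.  When references
  are made from a clean volume rather than from a reconstruction of the
  same data, they are weighted by the dataset-average CTF squared
  (`ctf_weight_volume()`); otherwise low-frequency mismatch dominates
  the correlation and tilt discrimination collapses.
* **Reference filtering.**  The working volume is low-passed (default
  4 x pixel size) before projection, suppressing the model bias that
  builds when segments are matched against a reconstruction of
  themselves.  The filter must stay finer than the 1-start pitch — the
  pitch layer line is the main orientation cue.
* **Multi-operator symmetry search.**  The mismatch between a volume
  and its copy under one symmetry operator is almost flat in (twist,
  rise) on noisy reconstructions: a twist error `e` misregisters the
  nearest neighbor by only `r * e`.  `hsearch()` therefore averages the
  residual over operator powers `k = 1..n_ops` (the loop uses 8), which
  sharpens sensitivity about eightfold; the residual itself is
  evaluated symmetrically (half-operator transforms of both sides) so
  interpolation smoothing cancels and the minimum is unbiased.
* **Noise-baseline subtraction.**  Correlated reconstruction noise
  prefers small operators (nearby voxels correlate), biasing the search
  toward small twist and rise.  A second back-projection with
  azimuths scrambled deterministically (golden-angle sequence) has the
  same noise statistics but no coherent helix; subtracting its residual
  surface removes the trend.
* **Bounded symmetrization.**  Averaging over many operators is only as
  good as the symmetry estimate: a rise error `dr` misregisters the
  k-th copy by `k * dr`.  Imposition averages at most `max_ops = 12`
  operator indices per voxel (sources restricted to the central 60
  percent of the box), trading noise averaging against the feedback
  amplification of estimate errors.
* **Per-cycle centering.**  Helical symmetrization about the box axis
  is only valid for a centered filament; reconstructions drift off-axis
  by a voxel or more, so every cycle recenters the map on its in-plane
  center of mass before imposition.
* **Back-projection weighting.**  Views cluster around the filament
  axis, so images are ramp-filtered across the filament axis (the
  classical single-axis weighting) before voxel-driven back-projection.
* **Degenerate searches.**  A featureless volume (the solid-cylinder
  start) yields a residual independent of the rise; `hsearch()` detects
  that (rise variation within twist rows below 1e-3 of the surface
  maximum) and raises a `degenerate_search` condition instead of
  returning an arbitrary answer.  Starting from a cylinder, the loop
  tolerates this for `hold_sym_cycles` cycles with the symmetry held
  fixed.
* **Convergence.**  The loop reports convergence when twist and rise
  change by less than 0.05 degrees and 0.02 A over three consecutive
  cycles — the refinement literature plots trajectories but states no
  criterion, so this one is explicit.

## Validation choices

* The B-factor convention is `exp(-B f^2 / 4)` on amplitudes; a
  negative B sharpens, so the standard post-processing pipeline is
  `amplitude_correct(vol, ctfs, bfactor = -2000, lowpass_ang = 12)`
  with a Wiener guard of 0.1 x mean(sum CTF^2) protecting the division.
* The low-pass edge is a two-shell cosine placed entirely below the
  cutoff, so power beyond the nominal resolution is removed completely.
* FSC uses one-voxel shells; the threshold resolution interpolates the
  first downward crossing that is sustained for two shells — isolated
  negative shells occur in sparse low-frequency shells of masked
  filament maps and should not set the resolution.
* A helical reconstruction is only defined up to rotation about and
  translation along its axis.  `align_helical_volume()` searches that
  gauge (coarse grid, then local refinement) before any map-vs-truth
  FSC; without it the comparison measures the arbitrary lattice phase,
  not map quality.
* Model maps are rasterized with Gaussian width `resolution/pi` and
  then low-passed at the target resolution; the cylindrical average
  bins by one-voxel radius, and the axial-hole metric divides the
  voxel-weighted core density (radius below 5 A by default, matched to
  the 12 A filtering scale) by the peak of the radial profile.
* Half-set comparisons split segments even/odd by segment id.

## Standard study conditions

The package's own studies (its test suite) run at two scales, chosen as
realistic desk-scale versions of the reference acquisition geometry:

* **Refinement studies**: 300 segments, 96-px boxes at 4.6 A/px, SNR
  0.1, out-of-plane tilt sigma 8 degrees truncated at +-16 so that the
  tilt-aware reference grid (+-16 in 4-degree steps) covers the data —
  emulating the practice of excluding very-large-tilt segments before
  final reconstruction.  References use an 8-degree azimuth grid; on
  this geometry back-projection from grids of 8 degrees or finer shows
  no measurable twist bias, while 10-degree grids do.
* **Tilt-sorting studies**: 300 segments at the acquisition geometry
  (192-px boxes, 2.3 A/px, tilt sigma 12 truncated at +-35, SNR 0.2),
  phase-corrected, two-fold decimated, and matched against the
  990-projection reference grid (4-degree azimuths, tilts -20..20 in
  4-degree steps).
* The wrong-symmetry demonstration imposes the C3 / -53.6 deg / 16.8 A
  lattice on data generated with -101.1 deg / 5.1 A.  These two are the
  textbook ambiguous pair: the C3 ring rise (16.8 A) nearly equals the
  1-start pitch of the true lattice (18.2 A), so both explain the same
  strong layer line.  The wrong refinement settles into a stable C3
  solution whose gauge-aligned map-vs-truth FSC resolution is at least
  twice worse than the correct run's.

## Known limitations

* Orientation assignment is hard (best-match) rather than
  probabilistic, as in the classical procedure; no multi-class sorting
  of mixed symmetries.
* The simulator draws segments as independent views sharing per-filament
  parameters; it does not model the spatial correlation of noise along
  one filament, flexibility, or picking errors.
* Absolute hand is not determined — layer-line positions cannot fix it,
  and both hands are returned by `candidate_symmetries()`.
* Real-space trilinear interpolation bounds the useful resolution to
  roughly three pixels; all studies here operate at 12–18 A scales
  where that is immaterial.
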