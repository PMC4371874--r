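Package: helixamb
Title: Diagnosing Helical-Symmetry Ambiguities in Cryo-EM Filament
    Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring why iterative helical real-space
    reconstruction (IHRSR) of cryo-EM filament images can converge to a
    stable but incorrect helical symmetry. Provides closed-form helical
    lattice mathematics (symmetry operators, layer-line prediction from
    the helical selection rule, Bessel-order peak positions and the
    out-of-plane tilt at which off-meridional layer-line peaks collapse
    onto the meridian), a synthetic cryo-EM generator (helical volumes
    from Gaussian subunits, tilted projections, contrast transfer
    function modulation, calibrated noise), power-spectrum and
    layer-line diagnostics, reference-projection matching over azimuth
    and out-of-plane tilt with tilt histograms, a full IHRSR refinement
    loop with helical symmetry search and imposition, and validation by
    Fourier shell correlation, model rasterization and cylindrical
    averaging. Volumes and image stacks are read and written as MRC2014
    mode-2 files; tables as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    bio3d
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
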