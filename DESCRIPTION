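Package: laminarbold
Title: Cortical-Depth-Dependent BOLD fMRI Analysis and Extravascular Field Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for laminar (cortical-depth-dependent) analysis of
    block-design BOLD fMRI, aimed at developmental studies comparing
    neonatal and adult haemodynamic responses at high field. Provides a
    synthetic 4D BOLD generator with age-specific response shapes,
    depth-dependent amplitudes, drift, noise and head motion; minimal
    preprocessing (slice-timing interpolation, discrete-cosine high-pass
    filtering, confound regression, RMS outlier detection, motion-based
    trial censoring); voxelwise GLM activation mapping with optional AR(1)
    prewhitening and percent-signal-change conversion; equivolume depth
    binning and column segmentation of a cortical ribbon with
    deep-depth-driven column selection; trial extraction, baseline
    conventions, depth-ratio statistics and rank-based group comparison
    (Kruskal-Wallis with Dunn post-hoc tests); and an infinite-cylinder
    model of extravascular magnetic field perturbations around veins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
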