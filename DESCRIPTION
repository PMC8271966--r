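Package: afpsim
Title: Monte Carlo Fluence and Photoacoustic Field Modelling for Annular
    Fiber Interstitial Illumination Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelized Monte Carlo photon transport for characterizing
    interstitial illumination probes used in photoacoustic guidance of
    radiofrequency ablation. Provides annular multi-fiber and surface launch
    geometries, liver optical-property presets with the reduced-scattering
    conversion, the depth-resolved fluence-homogeneity statistic (NFR_rel)
    with optimal-depth analysis, a perturbative photoacoustic forward model
    for field-of-view characterization, ROI-based signal-to-noise metrics
    for photoacoustic and ultrasound images, and synthetic phantom and scene
    generators so the full pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
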