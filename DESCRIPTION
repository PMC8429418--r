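Package: pdtplanr
Title: Interstitial Photodynamic Therapy Planning for Spinal Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based treatment planning for interstitial
    photodynamic therapy (PDT) of spinal metastases. Builds labelled
    voxel phantoms of a metastatically involved vertebra, runs voxel
    Monte Carlo photon transport with Henyey-Greenstein scattering and
    Fresnel interfaces to obtain per-source fluence kernels at the two
    BPD-MA activation wavelengths (690 nm and 565 nm), allocates
    per-source energies by convex optimization under a PDT threshold
    dose model, and evaluates plans through dose-volume histograms,
    tumour coverage, organ-at-risk damage volumes, and treatment-time
    estimates.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
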