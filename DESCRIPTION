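Package: flashpet
Title: In-Beam PET Simulation and Beam Localization for FLASH Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for verifying ultra-high-dose-rate (FLASH) proton beam
    delivery with a multi-panel in-beam positron emission tomography (PET)
    scanner. Provides an analytic model of positron-emitter activation and
    decay (isotope inventories, activity curves, window-integrated decay
    budgets, solid-angle detection efficiency), a seeded synthetic list-mode
    event generator standing in for the experiment (annihilation sampling,
    back-to-back photon transport onto a dodecagonal panel ring, energy and
    timing blur, per-panel-pair dead time, uncorrelated background),
    distributed per-panel-pair coincidence sorting with multiples removal and
    energy windowing, list-mode MLEM image reconstruction over a Siddon
    ray-traced system model, and 3D beam localization (depth-summed lateral
    peak, depth profiles, R50 distal-falloff range estimation, profile
    agreement metrics).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
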