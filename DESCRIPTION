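Package: pgcam
Title: Two-Plane Compton Camera Toolkit for Prompt-Gamma Range Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image-reconstruction toolkit for prompt-gamma (PG)
    range verification in proton therapy with two-plane scatter-absorber
    Compton cameras. Provides a simplified photon-transport Monte Carlo
    (Klein-Nishina Compton scattering, photoelectric absorption and pair
    production in scintillator crystals, attenuation-only phantom transport),
    a detector response model (energy, position and timing resolution with
    per-crystal thresholds), coincidence building with truth labelling,
    time-of-flight and add-back energy-window event selection, a
    gradient-boosted classifier that identifies full-energy coincidences,
    three Compton image-reconstruction algorithms (cone back-projection,
    stochastic origin ensemble, and an analytical spherical-harmonics
    inversion with precomputed angular moments of the Klein-Nishina cross
    section), and distal fall-off metrics (maximum, F90/F80/F50 positions)
    of one-dimensional beam-axis emission profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    xgboost,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
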