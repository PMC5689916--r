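Package: brachychar
Title: Monte Carlo Dosimetric Characterization of Low-Energy Brachytherapy Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale dosimetric characterization of low-energy (I-125)
    interstitial brachytherapy seeds in the AAPM TG-43 formalism. Provides a
    parametric capsule/marker seed geometry with ray-tracing queries, an
    analog photon Monte Carlo transport code with a track-length collision
    kerma estimator and axisymmetric ring tallies, extraction of the TG-43
    quantities (air-kerma strength, dose rate constant, radial dose function
    with fifth-order polynomial fit, 2-D anisotropy function, PMMA-to-water
    phantom conversion factors), a synthetic thermoluminescent-dosimeter
    measurement arm with a configurable noise model, and Type A/B uncertainty
    budget bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
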