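Package: npder
Title: Kilovoltage Photon Monte Carlo for Nanoparticle Dose Enhancement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale analog Monte Carlo transport of kilovoltage x-ray
    photons through a water phantom loaded with heavy-metal nanoparticles
    (gold, platinum, iodine, silver, iron oxide), with kerma-approximation
    voxel dose scoring. Builds filtered x-ray tube spectra from a Kramers
    bremsstrahlung model, composes water/nanoparticle mixtures via the
    Bragg additivity mixture rule over embedded elemental photon
    cross-section tables, and reduces central-axis depth doses to the
    dose enhancement ratio (DER) versus depth, the primary observable of
    orthovoltage nanoparticle-enhanced skin therapy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
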