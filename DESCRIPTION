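Package: nanotherm
Title: Monte Carlo Simulation of Gold-Nanorod-Mediated Photothermal Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-based simulator for laser interstitial photothermal
    therapy enhanced by plasmonic gold nanorods. Computes quasi-static
    (Gans) absorption cross sections of nanorods with a size-corrected
    Drude dielectric function, transports optical photons through
    voxelized tissue phantoms by analog Monte Carlo with tissue
    absorption, Henyey-Greenstein scattering and a nanoparticle
    absorption channel, converts deposited photon energy to temperature
    rise, and evolves the temperature field with the analytic Green's
    function solution of the Pennes bioheat equation. Ships synthetic
    pancreas-tumor and water-drop benchmark scenarios, virtual
    temperature probes and plane maps, and Analyze-style voxel-map I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    oro.nifti,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
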