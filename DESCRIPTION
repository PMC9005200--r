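Package: photonmc
Title: Monte Carlo Radiative Transport in Layered Turbid Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Monte Carlo simulation of photon migration through layered
    turbid media with an optional ellipsoidal inclusion. Implements analog,
    discrete and continuous absorption weighting random walks,
    Henyey-Greenstein and bidirectional phase functions, Fresnel boundary
    physics, Russian roulette, a catalogue of reflectance, transmittance and
    absorption detectors with rigorous second-moment variance reporting,
    photon-exit trajectory databases with post-processing, perturbation and
    differential Monte Carlo reweighting, and a gradient-based inverse
    solver that recovers tissue optical properties from spatially resolved
    reflectance. The transport kernel is written in C++ for speed; all
    results are returned as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
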