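Package: uatpe
Title: Modelling Ultrasound-Assisted Aqueous Two-Phase Extraction of
    Grape-Pomace Polyphenols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising and simulating the simultaneous
    extraction and preliminary purification of phenolic compounds from
    grape pomace by ultrasound-assisted aqueous two-phase extraction.
    Fits the empirical binodal curve of alcohol-salt aqueous two-phase
    systems and classifies compositions into one- and two-phase regions;
    computes partition coefficients, phase recoveries, purity and
    percent-change statistics; forward-simulates intraparticle phenolic
    diffusion (Fick's second law in a sphere coupled to a finite
    well-stirred bath) with a conservative finite-volume scheme, estimates
    the effective diffusion coefficient by inverse fitting, and models its
    quadratic response surface in acoustic energy density and temperature;
    trains and evaluates a single-hidden-layer feedforward neural-network
    yield surrogate; and generates seeded synthetic factorial datasets so
    the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
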