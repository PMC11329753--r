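Package: carrierkin
Title: Exchange Kinetics and Biophysical State Analysis for Mitochondrial Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of solute-carrier transport experiments in proteoliposomes:
    fitting of radiolabel homo-exchange uptake curves to the exponential exchange
    equation, bi-reactant Michaelis-Menten analysis of initial rates, statistical
    discrimination of ping-pong versus sequential (ternary-complex) exchange
    mechanisms, melting-temperature extraction from differential scanning
    fluorimetry traces, and oligomeric-state assignment from size-exclusion
    chromatography with lipid/detergent micelle correction. Includes a mechanistic
    two-pool tracer simulator for generating realistic synthetic experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
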