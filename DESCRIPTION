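Package: protoncal
Title: Medium-Thickness-Dependent Proton Dose Calibration for Cell
    Irradiation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale condensed-history Monte Carlo transport of 10-35 MeV
    protons for cellular dosimetry. Provides Bethe electronic mass stopping
    powers, CSDA ranges and Bohr/Vavilov-limit energy-loss straggling for
    water, cellular tissue, PMMA, glass and dry air; transports protons
    through a nine-cell adherent monolayer (half-ellipsoid cells with
    ellipsoidal nuclei) under a variable water medium layer and through a
    Farmer-type PMMA-walled ionization chamber; and tabulates the
    calibration coefficient R = D_A/D_E (cellular dose over detector dose,
    both in MeV/g per emitted source particle) as a function of incident
    proton energy and medium-layer thickness, including Bragg-peak
    thickness scans and peak finding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    ggplot2,
    generics,
    rlang,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
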