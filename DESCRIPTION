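Package: cinnamr
Title: NMR Fingerprinting, Quantification and Safety Screening of Cinnamon
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative proton-NMR workflow for authenticating commercial
    cinnamon (Cinnamomum burmannii, C. cassia, C. verum). Simulates 400 MHz
    1D 1H-NMR spectra with known metabolite content, converts spectra into
    solvent-excluded, bucketed and 1-100 normalized fingerprints, clusters
    fingerprints hierarchically by species, quantifies sixteen catalogued
    metabolites in mg/g by external reference-signal calibration (qNMR),
    classifies species by principal-component ordination and nearest-centroid
    assignment, and screens coumarin content against the tolerable daily
    intake of 0.1 mg per kg body weight. Ships a 48-sample reference
    concentration table and a versioned metabolite catalogue.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    stats,
    utils,
    ape,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
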