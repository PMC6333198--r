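Package: osldose
Title: Calibration and Uncertainty Analysis for OSLD-Based CT Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computed-tomography point dosimetry with optically
    stimulated luminescent dosimeters (OSLD, e.g. the Al2O3:C nanoDot).
    Implements depletion-, sensitivity- and background-corrected signal
    estimation from repeated reads, ion-chamber dose to water under the
    TG-111 formalism, three dosimeter calibration protocols (vendor
    standards, free-in-air CT beam, and megavoltage Co-60), beam-quality and
    geometry correction-factor tables with energy interpolation, and an
    exact-moment uncertainty engine that propagates variances through
    products of random variables without a normality assumption, validated
    by a seeded Monte Carlo oracle. A synthetic-data module generates
    reader count sequences and chamber readings with realistic noise so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
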