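Package: silylms
Title: Silylation Mass Spectrometry: Series Prediction, Formula
    Enumeration and Derivatization Cross-Checking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Interpretation tools for mass spectra of silylated small
    molecules (TBDMS/TMS derivatives of flavonoids and other
    polyphenols). Predicts m/z for derivatization series under ESI
    adduct rules and EI radical-cation rules, enumerates candidate
    elemental compositions from accurate mass under element bounds,
    narrows parent formulas by cross-checking candidate sets across
    derivatization degrees, annotates peak lists with predicted species
    and neutral-loss fragments, and quantifies derivatization
    efficiency from relative intensities. Includes a synthetic-spectrum
    generator for ESI peak lists and unit-resolution EI spectra so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
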