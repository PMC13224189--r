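Package: prefsolv
Title: Preferential Solvation Analysis of Solvatochromic Indicators in Binary Solvent Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing preferential solvation of a solvatochromic
    indicator dissolved in binary solvent mixtures. Converts absorption maxima
    to molar transition energies, fits Kamlet-Abboud-Taft linear solvation
    energy relationships to solvent descriptor panels, computes model-free
    first-solvation-shell compositions and the preferential solvation parameter,
    fits the Bosch-Roses two-step solvent-exchange model family (with
    intersolvent-complex and water-structure correction terms) by seeded
    multi-start nonlinear least squares, and estimates solute-solvent
    interaction-energy differences through the statistical cell model of
    ternary solutions. A seeded synthetic-data generator reproduces the
    statistical structure of titration experiments so every stage of the
    pipeline is verifiable without raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lhs,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
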