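Package: fretquant
Title: Quantitative In-Solution FRET Assays: Cross-Talk Correction,
    Binding Constants and Inhibitor Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state sensitized-emission FRET quantification for
    multi-well plate-reader data. Reads wavelength-resolved emission and
    absorbance scans, performs background correction and replicate
    averaging, determines fluorophore-to-protein labeling ratios from
    conjugate absorbance, estimates donor bleed-through and acceptor
    direct-excitation ratio factors, decomposes the acceptor-channel
    signal into its FRET component, fits a one-to-one ligand-depletion
    binding isotherm for the dissociation constant, and ranks competitive
    inhibitors by inhibition efficiency with replicate statistics. A
    physically structured synthetic-spectra generator emulates the full
    assay (emission bands, binding equilibria, competitive inhibition,
    cross-talk and replicate noise) so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
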