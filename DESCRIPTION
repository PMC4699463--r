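Package: fneoscreen
Title: Fluorescent Displacement Screening of miRNA-Binding Compound Libraries
Version: 0.1.0
Authors@R:
    person("fneoscreen", "developers", email = "fneoscreen@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of fluorescein-aminoglycoside (F-neo)
    displacement assays for RNA-binding compound libraries. Implements the
    tight-binding quadratic isotherm for probe K_D determination with ligand
    depletion, binding-site stoichiometry selection, competitive two-ligand
    one-site equilibrium, fluorescein protonation (pKa) fitting and the
    pKa-shift conversion to an apparent electrostatic potential of the binding
    site, Z'-factor assay quality control, per-plate neomycin-normalized
    percent-binding screens with hit calling, positional amino-acid preference
    statistics (sigma ledger) for peptidic-aminoglycoside conjugate libraries,
    seeded synthetic plate and titration generators, a dot-bracket bulge
    counter, and a command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
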