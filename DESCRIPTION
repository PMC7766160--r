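Package: fluorbind
Title: Fluorescence Quenching and Binding-Density Analysis of
    Protein-Ligand Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing protein-ligand complex formation from
    steady-state and time-resolved fluorescence titrations and circular
    dichroism spectra. Implements inner-filter correction, Stern-Volmer
    analysis with bimolecular quenching constants and a static-versus-dynamic
    mechanism classifier, TCSPC multiexponential lifetime fitting,
    double-logarithm binding-constant estimation, van't Hoff thermodynamic
    decomposition with Gibbs energies and driving-force classification, and a
    model-free binding-density (interaction density function) analysis with
    Scatchard diagnostics and Hill cooperativity fitting. A ground-truth
    two-site Adair simulator generates titration series, emission spectra,
    decay traces and CD spectra so that every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
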