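Package: riboswitchr
Title: Biophysical Prediction and Design of Protein-Sensing Translational Riboswitches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic modelling, sequence design and cell-free assay
    analysis for protein-sensing riboswitches that regulate translation
    initiation. Implements a five-term ribosome-mRNA binding free-energy
    model on top of ViennaRNA secondary-structure folding, evaluates the
    four predominant riboswitch states (protein-bound/unbound, with and
    without ribosome) to predict activation or repression ratios (R_max,
    R_conc, R_actual), designs pre- and post-aptamer sequences with a
    seeded multi-objective genetic algorithm, scans alternate aptamer
    structural subconstraints against measured ratios, and turns
    plate-reader kinetic fluorescence into corrected endpoints,
    dose-response fits and apparent Boltzmann-factor calibrations.
    Requires the ViennaRNA command-line tools (RNAfold, RNAduplex).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA (>= 2.4): RNAfold and RNAduplex on PATH
Config/testthat/edition: 3
RoxygenNote: 7.3.3
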