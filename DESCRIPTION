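Package: tdhomolog
Title: Evaluation of Top-Down Proteoform Identification with Homologous
    Protein Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation framework for top-down mass spectral
    proteoform identification against a homologous protein sequence database.
    Generates a reference proteome, a homologous proteome with controlled
    numbers of substitutions, insertions and deletions per protein, intact
    proteoforms with terminal truncations and at most one modification, and
    deconvoluted MS/MS spectra with peak dropout and ppm-scale mass error.
    Identifies proteoform-spectrum matches allowing one unknown mass shift
    against a concatenated target-decoy database with spectrum-level FDR
    control, maps reference identifications onto homologous protein segments
    by Smith-Waterman local search followed by global-local (semi-global)
    alignment with BLOSUM62, and computes correct-protein and correct-segment
    rates per mutation-count subgroup together with mass-shift localization
    accuracy and sequence-identity histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
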