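Package: hicplaid
Title: Hi-C Compartment and TAD Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("hicplaid", "developers", role = c("aut", "cre"),
    email = "devel@hicplaid.invalid")
Description: An integrative Hi-C analysis toolkit: restriction-site binning,
    contact-matrix construction, bin filtering and iterative correction (ICE),
    A/B compartment calling via observed/expected correlation PCA with
    histone-mark sign orientation, TAD boundary detection from z-score
    separation (insulation) scores with rank-sum significance and Bonferroni
    correction, compartment-switch classification coupled to gene expression,
    TAD conservation statistics, and a position-weight-matrix scan with
    dinucleotide-shuffled background for boundary motif enrichment. A
    synthetic contact-map generator with planted compartments, TADs, biases
    and expression effects provides ground truth so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
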