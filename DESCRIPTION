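Package: k2pgate
Title: Annotation, Gain-of-Function Design and Gating Simulation for
    Two-Pore Domain Potassium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with two-pore domain potassium (K2P) channel
    sequences. Locates the canonical K2P architecture (two pore domains with
    selectivity filters SF1/SF2 and pore helices Ph1/Ph2, four transmembrane
    helices TM1-TM4) from selectivity-filter motifs and Kyte-Doolittle
    hydropathy; assigns the TM2.1-TM2.6 residue numbering anchored on the
    glycine-hinge (GIP) motif of the second transmembrane helix; computes
    per-column conservation and sequence-logo information content for channel
    alignments; designs graded gain-of-function substitution series at the
    TM2.6 position together with minimal-base-change codon edits; and
    simulates Markov single-channel gating with half-amplitude idealization
    to relate open-probability changes to whole-cell currents. A synthetic
    fixture generator provides ground-truthed channels, coding sequences,
    alignments and gating traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
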