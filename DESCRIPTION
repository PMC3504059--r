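Package: tritax
Title: Three-Item Statement Representation of Phylogenetic Character Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts conventional phylogenetic character matrices (binary,
    ordered multistate, unordered multistate including DNA, RNA and amino
    acid alignments) into three-item statement (3TS) matrices. Supports the
    general (G) representation by exhaustion of the outgroup value, the
    Williams (W) fixed-outgroup representation and its binary-notation
    variant (WS), and additive (Farris) decomposition of ordered characters
    with optional per-character deduplication. Statements can be weighted
    uniformly, by Nelson-Ladiges fractional weighting, or by a fixed-outgroup
    fraction, all in exact rational arithmetic. Output is written as
    simplified NEXUS (with an ASSUMPTIONS wtset block), relaxed or strict
    PHYLIP, and CSV, together with a provenance sidecar, and a command-line
    front end mirrors the short-flag invocation style of legacy converters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
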