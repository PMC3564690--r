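Package: StructuredMotifs
Title: Exact Two-Stage Discovery of Structured DNA Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact enumeration of structured motifs (ordered tuples of
    mismatch-tolerant boxes separated by bounded gaps) in sets of DNA
    sequences, as they arise when modelling composite transcription factor
    binding sites. Stage one enumerates every simple motif per box template
    under the Hamming-distance model, with complete sorted occurrence
    lists; stage two assembles them into structured motifs by successive
    occurrence-list intersection with distance and quorum checks,
    optionally reordering boxes by occurrence mass or slicing candidate
    sets to bound memory. Includes a planted-motif benchmark generator
    with ground truth for recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
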