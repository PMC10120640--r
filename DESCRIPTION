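Package: plasmidDS
Title: Design Similarity Analysis of Genetic Part Variants in Engineered
    Plasmid Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects non-canonical variants of genetic parts (origins of
    replication, coding sequences, promoters, and other elements) across a
    corpus of engineered plasmids and classifies each variant as widespread
    (deposited by many independent labs) or recurrent (multiple independent
    origins inferred from sequence context). Plasmid pairs carrying the same
    variant are compared with an inverse-document-frequency-inspired Design
    Similarity (DS) score computed from the corpus frequencies of their
    shared sequence segments, the score is calibrated against a cross-lab
    null distribution, and connected components of the thresholded
    relatedness graph estimate how many times a variant arose independently.
    Includes a gapped local-alignment engine with BLASTN-like scoring, a
    synthetic multi-lab corpus simulator with known ground truth, and an
    end-to-end prioritization pipeline producing a variant catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
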