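Package: cmthread
Title: Protein Fold Recognition by Spectral Contact Map Threading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fold recognition for proteins whose structure cannot be found by
    sequence homology. A query's predicted residue-residue contact map is
    compared against a library of contact maps derived from known structures
    by aligning truncated eigendecompositions of the two maps with global
    dynamic programming, greedily resolving eigenvector sign ambiguity to
    maximise contact map overlap, and ranking templates with a
    correlation-based statistic and an optional logistic match-probability
    model. Includes readers for PDB, CASP-RR contact lists, PSIPRED ss2 and
    FASTA files, a versioned fold-library container, a deterministic
    synthetic-protein generator for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
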