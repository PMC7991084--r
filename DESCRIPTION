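Package: TCRMatchR
Title: Epitope-Specificity Matching of T-Cell Receptor CDR3 Sequences by
    k-mer Kernel Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores similarity between T-cell receptor CDR3 amino-acid
    sequences with a normalized BLOSUM62 frequency-matrix k-mer kernel
    (the TCRMatch score) and six comparison metrics (Needleman-Wunsch
    alignment score and identity fractions, Levenshtein distance, and a
    CDR3-only TCRdist), matches query CDR3beta sequences against a
    reference database of receptor groups with known epitope
    specificities, and benchmarks metrics with pooled precision/recall
    curves, ROC points, partial area under the precision-recall curve,
    and bootstrap comparisons. Includes IMGT-style flank trimming, a
    reference-database model with the standard assembly filters, a
    shuffled chance control, paired CDR3alpha-CDR3beta assembly and
    score averaging, and a seed-deterministic synthetic repertoire
    generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
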