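Package: timgo
Title: Two-Layer Machine Learning Prediction of 35S Enhancer Target Gene
    Activation in T-DNA Insertion Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a CaMV 35S enhancer carried on an inserted
    T-DNA activates a flanking target gene, from the gene promoter sequence,
    the enhancer-gene intervening sequence, and the enhancer-gene distance.
    Implements nine DNA feature encodings (CpG islands, cis-element motif
    scanning, k-mer and reverse-complement k-mer composition, dinucleotide
    and trinucleotide physicochemical properties, auto-cross covariance, and
    pseudo k-tuple nucleotide composition), distance-based logistic weighting
    of promoter features, t-test fragment selection, a first layer of 16
    per-feature support vector machines, mRMR plus incremental selection of
    the resulting meta-features, and a LogitBoost alternating decision tree
    (LADTree) second layer. Ships a synthetic-data generator emulating
    activation-tagging mutant panels so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
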