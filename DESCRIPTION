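Package: delpath
Title: Pathogenicity Prediction for Short Sequence-Retaining Protein Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable classifier for the clinical interpretation of short
    (1-10 amino acid) in-frame protein deletions that leave the downstream
    sequence intact. Provides readers for protein FASTA, deletion-variant
    tables (including HGVS-p deletion notation) and annotation intervals;
    engineered context, content, position and gene-level features (sequence-logo
    bit scores, physicochemical averages, functional-region overlaps,
    protein-interaction network centralities); a redundancy-aware feature
    filtering cascade; protein-disjoint split and fold ensemble training with
    recursive feature elimination and hyperparameter search; bootstrap-based
    three-state classification that abstains on variants of uncertain
    significance (VUS); and a complete evaluation suite with class-normalised
    confusion counts, MCC and the composite OPM score. A synthetic-data
    generator emulates the statistical structure of curated deletion datasets
    so the whole pipeline can be exercised without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xgboost,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ranger,
    e1071,
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
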