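Package: lecifr
Title: Cross-Species Functional Genomic Conservation Scoring with
    Pseudo-Siamese Network Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores evidence of conservation at the functional genomics
    level for pairs of sequence-aligning genomic regions in two species
    (the LECIF score). Parses pairwise 'axt' alignments into gap-free
    blocks and 50-bp paired regions, builds per-species feature vectors
    from peak calls, chromatin-state segmentations and signal tracks,
    trains an ensemble of two-branch (pseudo-Siamese) neural networks to
    separate aligning pairs from randomly mismatched pairs, and provides
    the statistics used to characterise such scores: class-weighted
    AUROC/AUPRC, weighted Jaccard similarity of tissue-grouped peak
    activity, chromatin-state frequency correlation, variant enrichment
    with binomial tests, and windowed score comparisons. Includes a
    synthetic two-genome generator with planted cross-species concordance
    so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    glmnet,
    ranger,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
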