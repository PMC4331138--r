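Package: qualmer
Title: Quality-Weighted Alignment-Free Comparison and Clustering of
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free comparison of sequencing reads using k-mer
    count vectors weighted by per-base phred quality scores. Implements
    the classical D2, D2* and D2s word-count statistics together with
    their quality-weighted counterparts (D2^q, D2*^q, D2^sq), two
    dataset-level estimators of the expected word probability (average
    word probability and average quality probability), and optional
    redistribution of the missing quality mass of each base over
    single-substitution neighbour words. On top of the measures it
    provides centroid-based (k-means) clustering of reads with
    multi-restart and a no-improvement stopping rule, a recall-rate
    evaluation of clusterings against known read origins, and a
    quality-consistent read simulator for synthetic benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
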