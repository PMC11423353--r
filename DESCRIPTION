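Package: phagetools
Title: Alignment-Free Phylogenomics, Lifestyle Prediction and Annotation
    Comparison for Bacteriophage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for exploratory analysis of bacteriophage
    whole-genome sequences. Builds alignment-free phylogenies from k-mer
    feature-frequency profiles compared by Jensen-Shannon divergence and
    clustered with neighbor joining; classifies phage lifestyle (temperate
    versus lytic) from protein-domain presence/absence features with a
    cross-validated random forest; reconciles genome annotations produced by
    the Pharokka, PHASTER and RAST pipelines into common/unique comparison
    tables; and lays out and renders phylogenetic trees (phylogram,
    cladogram, fan, radial) as SVG with tip metadata coloring. Includes
    deterministic simulators for genomes evolved along a known tree,
    motif-implanted lifestyle datasets and annotation-file triplets, used as
    ground-truth oracles throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
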