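Package: apomir
Title: Small RNA Tag Processing and miRNA Inference for Contrasting Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for inferring microRNAs from small-RNA
    sequencing libraries of genotypes with contrasting phenotypes (for example
    apomictic versus sexual plant cultivars). Provides adapter and quality
    trimming with tag collapsing and minimum-count filtering, sequential
    subtraction of organellar and non-coding RNA contamination, homology-based
    classification of conserved miRNA families with consensus naming,
    degradation-aware discovery of novel miRNA candidates from transcriptome
    coverage profiles, plant-style miRNA-target complementarity scoring with an
    expectation penalty and optional site-accessibility filtering, an exact
    conditional negative-binomial test for count-based differential expression
    with Benjamini-Hochberg correction, and 2^-ddCt relative quantification of
    qPCR assays. A fully deterministic synthetic-library generator with planted
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
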