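Package: lncorange
Title: Discovery and Characterization of Flowering-Related lncRNAs in
    Trifoliate Orange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for discovering long non-coding RNAs
    (lncRNAs) from assembled transcripts of the precocious (early-flowering)
    trifoliate orange mutant (MT) and its wild type (WT). Implements the
    sequential filter cascade that separates lncRNA candidates from coding
    transcripts (similarity screens, length and open-reading-frame filters,
    a surrogate coding-potential score with hooks for externally computed
    scores, presence in both genotypes, and housekeeping/miRNA-precursor
    screens), positional classification of lncRNAs relative to coding genes
    (intergenic, intragenic, antisense), FPKM-based differential expression
    between genotypes, and prediction of miRNA-lncRNA interactions: cleavage
    target sites scored by a penalty scheme and endogenous target mimics
    (eTMs) detected by explicit bulge-and-pairing rules. A synthetic-data
    module generates miniature genomes, transcript sets, negative-binomial
    expression counts, and planted miRNA sites with full ground truth so the
    whole pipeline can be exercised and evaluated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
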