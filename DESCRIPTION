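Package: dwbiofilm
Title: Amplicon Diversity, Genome Binning and Functional Profiling for
    Drinking-Water Biofilm Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational workflow used to
    characterise drinking-water biofilm communities from 16S rRNA amplicon and
    shotgun metagenomic sequencing. Provides a synthetic-community generator
    (reference genomes, shotgun read pairs, contigs with coverage, barcoded
    amplicons, single-copy marker annotations), amplicon demultiplexing and
    primer trimming, complete-linkage OTU clustering with Chao1, Shannon,
    Pielou and rarefaction estimates, a naive-Bayes k-mer taxonomic classifier
    with bootstrap confidence, Illumina read quality filtering,
    de-replication and paired-read tag merging, coverage- and
    tetranucleotide-based genome binning with marker-gene completeness and
    redundancy scoring and bin abundance estimation, and PCA ordination of
    functional-category profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
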