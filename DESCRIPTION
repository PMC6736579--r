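Package: taxonsluice
Title: Blank-Informed Contaminant Screening and Amplicon-to-Genome Linking
    for Low-Biomass 16S rRNA Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control of low-biomass 16S rRNA gene amplicon
    surveys and for linking amplicon sequence variants to metagenome-assembled
    genomes (MAGs). Implements a multi-blank contaminant screen that flags
    OTUs whose depth-normalized abundance is concentrated in extraction
    blanks, annotates flagged OTUs against a reference 16S database with a
    seeded local-alignment search (percent identity, query coverage, e-value,
    environmental source of the closest matches), and applies a reviewed
    culling step. A second workflow recruits biofilm amplicons onto MAG 16S
    genes at configurable identity and coverage thresholds, screens the genes
    with a read-coverage uniformity QC, partitions MAGs into biofilm-linked
    and planktonic fractions, and compares ORF-normalized functional profiles
    and marker-gene presence between the fractions. A deterministic
    synthetic-data generator with recorded planted truth makes every step
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    Biostrings,
    rtracklayer,
    optparse,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
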