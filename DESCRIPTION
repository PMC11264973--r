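Package: astructr
Title: Allele-Specific RNA Secondary Structure Calling from RT-Stop Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects allele-specific RNA secondary structure (ASRS) at
    heterozygous SNPs from RT-stop based structure-probing sequencing data
    (icSHAPE/smartSHAPE). Partitions SNP-spanning reads by allele, computes
    per-allele per-base reactivity profiles by percentile-normalised
    enrichment of reverse-transcriptase stops over background, quantifies
    the allelic structure difference with the experimental structural
    disruption coefficient (eSDC) against a Poisson 1:1 read-permutation
    null, and combines magnitude, significance and spanning-read fraction
    into a composite score with Low/Medium/High grouping. Includes a
    synthetic read simulator with ground-truth paired/unpaired masks and
    ROC-based benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    pROC,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
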