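Package: lsblscan
Title: Selection-Signature Scanning and Population Diversity Analysis for
    SNP Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for population-genetic analysis of
    biallelic SNP genotypes from diverged livestock populations: site-level
    quality control (minor-allele-frequency and exact Hardy-Weinberg
    filters), genetic-diversity metrics (expected/observed heterozygosity,
    per-individual inbreeding F, windowed nucleotide diversity, PLINK-style
    runs of homozygosity), linkage-disequilibrium decay with Sved-equation
    effective population size, population structure (Patterson-scaled PCA,
    identity-by-state distances, neighbor-joining trees), and
    selection-signature scans built on the Weir-Cockerham Fst estimator:
    three-population locus-specific branch lengths (LSBL) with top-quantile
    region calling and fine-scale rescans, and a two-group Fst and
    nucleotide-diversity-ratio overlap scan. A three-population
    Balding-Nichols genotype simulator with haplotype-mosaic linkage,
    injected selective sweeps and homozygous tracts provides a recoverable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
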