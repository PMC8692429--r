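Package: vitipop
Title: Population Genomics of Grapevine Domestication Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic analyses for diploid resequencing
    cohorts of cultivated and wild grapevine (Vitis vinifera): a multi-rule
    genotype-call filter cascade keyed to per-sample modal coverage, windowed
    identity-by-descent profiling and pedigree-relationship classification,
    outgroup polarization with unfolded site-frequency spectra, ABBA-BABA D
    and adjusted f_d introgression scans with block-jackknife errors, Nei D_A
    window-topology scans, three-population tests, nucleotide and haplotype
    diversity scans with selective-sweep detection, runs of homozygosity,
    iterative regional haplotype inference, and Stouffer meta-analysis of
    allele-specific expression. Includes a pedigree-aware diploid cohort
    simulator with full ground truth so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
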