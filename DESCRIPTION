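Package: nmdscreen
Title: Ratiometric NGS Screening and Recovery Analysis for Nonsense-Mediated Decay Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plate-based, dual-barcoded amplicon sequencing screens that
    read out nonsense-mediated decay (NMD) inhibition as a mutant allele fraction
    (MAF) in a pooled panel of isogenic knockout clones. Provides streaming FASTQ
    demultiplexing by plate and well barcodes, allele-specific read classification
    against a mutant/wild-type amplicon panel, pool-corrected MAF statistics,
    control-calibrated hit calling (mean plus k standard deviations of vehicle
    controls, conjunction over all reporter alleles), plate-level quality control,
    a transcriptome-level mutant-transcript recovery analysis on treated versus
    control variant read counts (depth and zygosity filters, fold change, class
    stratification, two-proportion chi-squared testing), and synthetic-data
    generators with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
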