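Package: divscan
Title: Genomic Divergence Landscapes, Islands, and Environmental
    Association for Two-Species Resequencing Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic landscapes (nucleotide diversity,
    Weir-Cockerham F_ST, D_XY, moment-based population recombination rate)
    from biallelic SNP genotypes of two sister species; permutation-based
    detection of genomic islands of differentiation with
    Benjamini-Hochberg FDR control; copy-number differentiation via the
    V_ST statistic with label-permutation significance; an HKA-style
    polymorphism-versus-fixed-difference contingency test for positively
    selected genes; redundancy-analysis genotype-environment association
    with permutation-tested axes, 3-SD loading outliers and predictor
    assignment; and Mantel isolation-by-distance/environment tests on
    linearized F_ST. Includes a seeded synthetic-data generator that
    emulates a two-species resequencing design (Balding-Nichols
    differentiation, founder-haplotype linkage blocks, planted islands,
    copy-number-differentiated genes, selection targets and
    environment-associated variants) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
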