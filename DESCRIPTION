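Package: vntrcomp
Title: Sequence Composition and Length Analysis of 30-bp-Unit VNTR Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze a variable number tandem repeat (VNTR) built from
    a 30-bp unit: locate the repeat between unique flanking sequences, decompose
    alleles into repeat units, build prevalence-ranked variant catalogs, profile
    unit-variant proportions from assemblies or short reads, classify alleles
    into short and long sequence-composition classes (threshold and PCA/k-means),
    quantify perfect repeat tracts, test 1-bp mutational-neighborhood enrichment,
    call trio inheritance and de novo mutations by global affine-gap alignment,
    and associate the long-allele genotype with SNP haplotypes (LD r2, Hardy-
    Weinberg expectations) and gene expression (covariate-adjusted linear models
    with Bonferroni correction). Includes a seeded synthetic-data generator that
    emulates the diploid cohort structure the analysis assumes, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
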