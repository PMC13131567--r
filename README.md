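# vntrcomp

Analysis of sequence composition and length variation at a VNTR built from a
30-bp repeat unit — the intron-3 *CACNA1C* tandem repeat whose alleles fall
into two classes: short alleles (~6 kb) rich in one unit variant and long
alleles (~24–28 kb) rich in another, segregating on a single tagging
haplotype.

The package implements the full analysis as reusable, tested functions, and
ships a seeded synthetic-data generator that emulates the cohort structure
the analysis assumes, so every stage runs and is verifiable without any
external sequencing data.

## What it computes

Let an allele's interior be the sequence between its unique flanks,
decomposed into consecutive 30-bp units `u_1 … u_n` (fixed frame, anchored at
the 5′ flank). For a prevalence-ranked catalog of distinct unit sequences
(IDs 1, 2, 3, … by cohort count), the package computes:

- **Variant proportions** `p_v = #{i : u_i = v} / n`, from assembled alleles
  or from exact 30-mer counts in short reads, plus a normalized read-depth
  proxy for repeat length (locus reads per million).
- **Allele classification**: long-class iff `p_3 > 0.2` (the variant-3
  proportion threshold), and, at cohort level, PCA + 2-means clustering of
  the proportion matrix.
- **Perfect repeat tracts**: maximal runs of identical units; counts,
  proportions, and S-vs-L class comparisons (two-sample Kolmogorov–Smirnov
  on pooled tract lengths, Wilcoxon rank-sum on per-allele summaries).
- **Mutational neighborhood**: among units within Hamming distance 5 of
  variant 1 (variant 1 itself excluded), the fraction at distance exactly 1
  from variant 2 vs variant 3, compared between carriers and non-carriers,
  with rare-variant strata.
- **Trio inheritance**: global affine-gap alignment (match +1, mismatch −1,
  gap open −3, gap extend −0.5) of each child allele against the four
  parental alleles; the maximum score assigns inheritance, mismatch columns
  and gap segments count de novo events; founder labels propagate through
  multi-generation pedigrees.
- **Haplotype association**: LD as `r² = D²/(p_A(1−p_A) p_B(1−p_B))` over
  phased haplotypes, Hardy–Weinberg expected homozygotes `n q²`, and
  covariate-adjusted linear models of gene expression on L-allele dosage
  with Bonferroni correction.

## Worked example

```r
library(vntrcomp)

cfg    <- sim_config(seed = 42, n_individuals = 200, long_allele_freq = 0.1)
cohort <- simulate_cohort(cfg)
print(cohort)
#> Synthetic diploid cohort: 200 individuals; 47 L haplotypes; 400 simulated alleles
#> L/L S/L S/S
#>   1  45 154

## allele-level classification by the variant-3 threshold
profiles <- lapply(names(cohort$alleles), function(h)
  profile_from_units(cohort$alleles[[h]], cohort$catalog, subject_id = h))
classes <- vapply(profiles, classify_allele, "")
mean(classes == ifelse(cohort$hap_long, "L", "S"))
#> [1] 1

## cohort-level clustering view
cluster_two(profile_matrix(profiles), seed = 1)
#> Two-group composition clustering:
#> major minor
#>   353    47
#> mean variant-3 proportion: major = 0.108 ; minor = 0.2873

## perfect repeat tracts are longer and more abundant in the long class
compare_tract_classes(cohort$alleles[!cohort$hap_long],
                      cohort$alleles[cohort$hap_long])
#> Perfect-tract comparison (qualifying tracts >= 5 units)
#>   KS on pooled tract lengths: D = 0.4310, p = 0
#>   Wilcoxon, tracts per allele: U = 27.0, p = 7.08e-29
#>   Wilcoxon, proportion in tracts: U = 0.0, p = 7.98e-29

## the long class rides one tagging haplotype, at HWE
ld <- ld_scan(cohort$hap_long, cohort$snps)
ld$r2[cohort$tag_index]
#> [1] 1
hwe_expected_homozygotes(sum(cohort$hap_long), 200)   # observed: 1
#> [1] 2.76125

## expression association with L-allele dosage
expr <- simulate_expression(cohort, cfg)
scan <- association_scan(expr, cohort$individuals$dosage, expr$covariates)
head(scan[order(scan$p_value), c("gene", "estimate", "p_value", "p_bonferroni")], 1)
#>   gene  estimate      p_value p_bonferroni
#> 1 G001 -1.209761 7.871758e-13 3.935879e-11
```

All 400 alleles are recovered by both the 0.2 threshold and 2-means
clustering; the simulated tag SNP is in complete LD with the long-allele
indicator; the one observed L/L homozygote sits inside the Hardy–Weinberg
expectation of ~2.8; and the dosage-linked gene is the only
Bonferroni-significant association, with the configured negative effect.

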