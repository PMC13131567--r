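---
title: "Sequence composition and length at a 30-bp-unit VNTR: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence composition and length at a 30-bp-unit VNTR: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrcomp)
```

## The analysis

This package analyzes a variable number tandem repeat whose unit is 30 bp
and whose alleles are bimodal in two coupled ways: length (a short mode near
6 kb and a long mode near 24–28 kb) and unit composition (the short class is
rich in one single-base variant of the consensus unit, the long class in
another). The pipeline has six analytical stages, each a thin layer over the
data types `variant_catalog`, `tract_allele`, `variant_profile` and
`read_set`:

1. **Locate and decompose** (`locate_tract`, `decompose_tract`): the repeat
   interior is the sequence strictly between exact flank anchors (both
   strands searched; a probe unit variant must occur inside, otherwise the
   hit is rejected as a decoy locus). The interior is chunked into
   consecutive 30-base windows anchored at the 5′ boundary.
2. **Catalog and profile** (`build_catalog`, `profile_from_units`,
   `profile_from_reads`, `normalized_depth`): distinct unit sequences are
   ranked by cohort count; units retained when seen on average more than 0.2
   times per individual. Proportions are unit counts over counted units;
   from reads, every exact 30-mer window occurrence counts, both
   orientations.
3. **Classify** (`classify_allele`, `pca_scores`, `cluster_two`): an allele
   is long-class iff its variant-3 proportion strictly exceeds 0.2. At the
   cohort level, PCA (column-centered, unscaled; PC1 sign fixed by the
   variant-3 loading) and 2-means on the raw proportion matrix give the
   exploratory two-cluster view; the cluster with lower mean variant-3
   proportion is always named "major".
4. **Perfect tracts** (`find_perfect_tracts`, `compare_tract_classes`):
   maximal runs of identical units, compared between classes by KS on
   pooled per-tract lengths and Wilcoxon on per-allele counts/proportions of
   tracts of at least five units.
5. **Mutational neighborhood** (`neighborhood_profile`,
   `compare_carriers`): among units within Hamming distance 5 of variant 1
   (exact variant 1 excluded — it is one base from both variant 2 and
   variant 3 and would dominate both numerators), the fractions at distance
   exactly 1 from variant 2 and from variant 3, compared between carriers
   and non-carriers.
6. **Trios and association** (`assign_inheritance`, `count_de_novo`,
   `trace_founder_alleles`, `ld_r2`, `hwe_expected_homozygotes`,
   `association_scan`): global affine-gap alignment assigns each child
   allele to the max-scoring of the four parental alleles; LD r² is
   computed over phased haplotypes; expression is regressed on L-allele
   dosage with covariates and Bonferroni correction.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| unit size | 30 | bp | the repeat's motif length; decomposition frame |
| classification threshold | 0.2 | proportion | strict inequality on the variant-3 proportion separates the two composition modes, which sit ~9 within-class SDs on either side of it |
| catalog retention | > 0.2 | mean count/individual | drops sequencing-noise singletons while keeping rare real variants |
| neighborhood denominator | ≤ 5 | bp from variant 1 | captures rare variants beyond the catalog while staying in the motif's orbit |
| alignment scores | +1/−1/−3/−0.5 | per column / gap | a gap of length k costs 3 + 0.5(k−1); substitutions between unit variants cost less than unit indels, so unit-level copy changes surface as gap segments |
| qualifying tract size | 5 | units | tracts at least this long carry the class contrast |
| flank anchor | 20 | bp | exact-match anchor taken from each provided flank; ambiguity is an error, never silently resolved |

## The synthetic generator

`sim_config()` fixes the study conditions; all randomness flows from one
integer seed (sub-generators are seeded deterministically from it, so equal
seeds give byte-identical cohorts).

- **Lengths** are truncated normals (minimum 3,000 bp), rounded to whole
  units: short class median 5,932 bp, SD 1,045; long class median 27,798 bp,
  SD 11,653. The within-class distribution family is a modeling choice — the
  summaries pin only the location and spread.
- **Composition**: each allele draws per-allele variant-2 and variant-3
  proportion targets from the class means/SDs (S: 18.69% ± 2.42% and
  10.76% ± 1.07%; L: 7.26% ± 0.84% and 28.94% ± 1.01%), allocates exact unit
  counts to those targets, and gives variant 1 about a third of units in
  both classes. Residual mass goes to rarer catalog variants, weighted
  toward single-base neighbours of the class anchor (variant 2 for S,
  variant 3 for L, `neighbor_bias` = 12) — emulating descent of rare units
  from the class's dominant variant, which is what the neighborhood
  enrichment measures.
- **Runs, not i.i.d. units**: each variant's units are split into runs with
  geometric mean length `tract_run_scale` (2 for S, 6 for L) and shuffled.
  I.i.d. unit sampling cannot reproduce the long class's perfect-tract
  excess; run construction makes it a generator property. With
  `tract_run_scale = 1` runs of one unit are arranged with no same-variant
  adjacency, so no perfect tract of two or more units exists — a degenerate
  setting used to test maximality.
- **Cohorts** draw two allele classes per individual under Hardy–Weinberg
  with long-allele frequency 0.0304 (the long-read cohort allele fraction).
  One SNP tags the long allele: every L haplotype carries the tag and just
  enough S haplotypes are added to hit the target r² (default 1, complete
  LD — the single-origin haplotype scenario); remaining SNPs are
  independent.
- **Pedigrees** copy a random parental haplotype per transmission and apply
  Poisson-many single-base substitutions at distinct recorded positions
  (default rate 0, matching the observed absence of de novo changes);
  single-unit insertions/deletions are available behind
  `length_event_rate`.
- **Reads** are uniform over each haplotype (flanks + interior) at half the
  diploid depth per haplotype, with independent per-base substitution
  errors and random strand; the implied genome-wide read total is recorded
  for depth normalization.
- **Expression** adds `effect × dosage` (default −1, the direction of the
  long-allele association) to one target gene over covariate effects and
  unit-SD Gaussian noise.

What the generator does *not* emulate: sequencing indels and frame-shifted
units (decomposition reports such units as uncatalogued rather than
realigning them), mosaicism, population structure, LD decay along the SNP
window, and any evolutionary dynamics of expansion — it targets
extant-cohort structure only. Passing tests therefore certify the
*operations* (decomposition, statistics, alignment, inheritance logic)
under clean in-frame data, not robustness to assembly error.

## Numerical choices and degenerate inputs

- Decomposition is fixed-frame from the 5′ boundary; a trailing remainder
  shorter than one unit is kept as residual and excluded from counts, so
  `units + residual` always reconstructs the interior exactly.
- Catalog IDs are assigned by strictly non-increasing count with
  lexicographic tie-break — a deterministic, permutation-free ranking.
- `hamming` refuses unequal lengths (no alignment fallback): a
  frame-shifted unit is not a unit variant.
- Profile proportions sum to 1 within 1e−9 whenever defined; empty
  denominators are errors (`no-countable-units`), never silent zeros.
- k-means runs on raw proportions (not PC scores, not standardized), 25
  restarts, seed required; an all-identical input is flagged degenerate
  rather than silently split. Cluster naming by the variant-3 mean removes
  label permutation.
- Alignment ties are broken toward the lowest parent index and flagged —
  never silent. De novo events count mismatch *columns* plus gap *segments*
  (one length-change event per contiguous gap, since one mutational event
  inserts or deletes a block).
- LD at a monomorphic locus is reported as missing (`NA`), not 0.
- Exact Wilcoxon p-values (total n ≤ 12) come from full enumeration of
  group assignments over midranks, which stays valid under ties; larger
  samples use the tie-corrected normal approximation with continuity
  correction. Exactly-zero regression p-values are clamped to the smallest
  positive double so Bonferroni arithmetic stays in (0, 1].

## Design decisions taken where the design was open

- **Alignment backend**: global affine-gap alignment is delegated to
  Biostrings' C implementation, whose gap convention
  (`gapOpening + k × gapExtension`) reproduces the stated scoring exactly
  (verified: aligning `ACGT` to `ACG` scores 0). An explicit Gotoh dynamic
  program serves as the independent oracle in the tests. At the simulated
  allele sizes full dynamic programming is fast enough that no banded
  approximation is needed.
- **Read counting** is per 30-base window, not per read: a read containing
  two catalog units contributes two counts.
- **Tract pooling**: the KS comparison pools per-tract lengths across
  alleles within a class (per-allele weighting would be an alternative; the
  class contrast is a property of tract-length distributions).
- **Neighborhood numerators** count distance exactly 1 (not ≤ 1), so the
  statistic measures *neighbours* of variants 2/3, not the variants
  themselves; rare-variant strata use cohort-wide unit frequencies.
- **Homozygote upgrade**: with only individual-level carrier status, a
  carrier is upgraded to L/L when both phased haplotypes carry the tag —
  an operationalization of haplotype-cluster evidence, and an approximation
  when tagging is imperfect.
- **Bonferroni multiplicity** is genes × predictors within a run;
  cross-run correction is the caller's responsibility.

## Problem sizes used by the test suite

Cohort-scale guarantees are exercised at sizes chosen to make Monte-Carlo
bounds sharp while keeping the suite fast: 1,000 alleles for round-trip
decomposition; 10,000 alleles (94%/6% class mix) for classification
recovery by both threshold and 2-means; 1,000 random unit arrays against
the naive tract oracle; 512 pedigree transmissions with induced
substitution rates λ ∈ {0, 1, 2, 3} on ~900-bp interiors for inheritance
and de novo recovery; 200 random pairs up to 60 bases against the alignment
oracle; 1,000 Hardy–Weinberg cohorts of 500 individuals for the homozygote
envelope; 10,000 null replicates at n = 500 per group for KS/Wilcoxon
type-I calibration (at small n the KS test's discrete statistic puts its
achievable size visibly below the nominal level — a property of the test,
not of the implementation — so calibration is checked where the level is
meaningful); and 60 seeds for association power at effect −1, n = 500,
Bonferroni over 50 genes.

## Limitations

- Decomposition assumes in-frame alleles; indels shift the frame and
  surface as runs of uncatalogued units (reported, not corrected).
- The 0.2 threshold and the cluster view agree only when the two
  composition modes are well separated, as they are at the default
  parameters; cohorts with intermediate compositions would need the
  cluster boundary, not the fixed threshold.
- The carrier-upgrade rule inherits any tagging error of the SNP used.
- Read-based proportions are slightly biased at locus edges (windows
  clipped by read ends); with realistic flank lengths the effect is well
  below sampling noise.
- The generator's tagging model is one-sided (the tag allele contains all
  L haplotypes); r² targets below 1 are met approximately, not exactly.
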