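#' Default synthetic flanking sequences
#'
#' Fixed synthetic 60-base unique sequences attached 5' and 3' of every
#' simulated repeat interior. They stand in for the unique flanks that anchor
#' locus extraction; they contain no repeat unit and are shared by all
#' simulated haplotypes.
#' @name synthetic-flanks
#' @export
FLANK5_DEFAULT <- "TGCAAGTTCGATCCAGGTTACGAGTCTTGGAACCTTAGCTGTACCGATTGACGGAATCAC"

#' @rdname synthetic-flanks
#' @export
FLANK3_DEFAULT <- "CCTAGTGAAGCTTCAGGATCATGCCGTTAGTCAAGGTCCTAACGGTGCATTCGAAGTCCA"

#' Default class-conditional generator parameters
#'
#' Length and composition parameters for the short (S) and long (L) allele
#' classes; see [sim_config()] for their meaning.
#' @return A list with elements `S` and `L`.
#' @export
default_class_params <- function() {
  list(
    S = list(length_median_bp = 5932, length_sd_bp = 1045,
             variant1_mean = 0.33,
             variant2_mean = 0.1869, variant2_sd = 0.0242,
             variant3_mean = 0.1076, variant3_sd = 0.0107,
             tract_run_scale = 2),
    L = list(length_median_bp = 27798, length_sd_bp = 11653,
             variant1_mean = 0.31,
             variant2_mean = 0.0726, variant2_sd = 0.0084,
             variant3_mean = 0.2894, variant3_sd = 0.0101,
             tract_run_scale = 6)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator. The
#' class-conditional defaults are the cohort-level summaries the analysis
#' assumes: short (S) alleles with median interior 5,932 bp (SD 1,045), unit
#' composition 18.69\% +/- 2.42\% variant 2 and 10.76\% +/- 1.07\% variant 3;
#' long (L) alleles with median 27,798 bp (SD 11,653), 7.26\% +/- 0.84\%
#' variant 2 and 28.94\% +/- 1.01\% variant 3, and longer perfect repeat runs
#' (`tract_run_scale`, the mean geometric run length).
#'
#' @param seed Integer master seed; all generator randomness flows from it.
#' @param n_individuals Number of diploid individuals.
#' @param long_allele_freq Population frequency of the long (L) allele class;
#'   default 0.0304 (the long-read cohort fraction 18/592).
#' @param class_params Per-class parameter lists; see
#'   [default_class_params()] for the fields and defaults.
#' @param n_snps Number of biallelic SNP sites per haplotype.
#' @param tag_snp_r2 Target haplotype r-squared between the tag SNP and the L
#'   indicator, in `[0, 1]`; default 1 (a perfectly tagging haplotype).
#' @param de_novo_per_transmission Expected Poisson count of de novo
#'   single-base substitutions per transmitted allele; default 0.
#' @param read_length_bp,coverage_x,per_base_error Short-read model: read
#'   length (>= 30), diploid depth, per-base substitution error rate.
#' @param genome_size_bp Nominal genome size used to set the total read count
#'   for depth normalization.
#' @param expression_effect Additive expression effect per L allele on the
#'   target gene (default -1, expression units per dosage unit).
#' @param expression_noise_sd Residual SD of simulated expression.
#' @param n_genes,n_covariates Size of the simulated expression study.
#' @param min_length_bp Lower truncation of the allele length distributions.
#' @param n_catalog_variants Catalog size for [generate_catalog()].
#' @param neighbor_bias Multiplicative weight favouring mutational neighbours
#'   of variant 2 (in S alleles) or variant 3 (in L alleles) when distributing
#'   rare-unit mass; emulates descent of rare variants from the class anchor.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 100L,
                       long_allele_freq = 0.0304,
                       class_params = default_class_params(),
                       n_snps = 20L,
                       tag_snp_r2 = 1.0,
                       de_novo_per_transmission = 0,
                       read_length_bp = 150L,
                       coverage_x = 30,
                       per_base_error = 0.001,
                       genome_size_bp = 3.1e9,
                       expression_effect = -1,
                       expression_noise_sd = 1,
                       n_genes = 50L,
                       n_covariates = 3L,
                       min_length_bp = 3000,
                       n_catalog_variants = 50L,
                       neighbor_bias = 12) {
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              long_allele_freq = long_allele_freq, class_params = class_params,
              n_snps = as.integer(n_snps), tag_snp_r2 = tag_snp_r2,
              de_novo_per_transmission = de_novo_per_transmission,
              read_length_bp = as.integer(read_length_bp),
              coverage_x = coverage_x, per_base_error = per_base_error,
              genome_size_bp = genome_size_bp,
              expression_effect = expression_effect,
              expression_noise_sd = expression_noise_sd,
              n_genes = as.integer(n_genes),
              n_covariates = as.integer(n_covariates),
              min_length_bp = min_length_bp,
              n_catalog_variants = as.integer(n_catalog_variants),
              neighbor_bias = neighbor_bias)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!in01(cfg$long_allele_freq)) stop("long_allele_freq must be in [0, 1]")
  if (!in01(cfg$tag_snp_r2)) stop("tag_snp_r2 must be in [0, 1]")
  if (!in01(cfg$per_base_error)) stop("per_base_error must be in [0, 1]")
  if (cfg$de_novo_per_transmission < 0) stop("de_novo_per_transmission must be >= 0")
  if (cfg$read_length_bp < UNIT_BP) {
    stop("invalid configuration: read_length_bp < ", UNIT_BP,
         " cannot contain a full repeat unit")
  }
  if (cfg$min_length_bp <= 0) stop("min_length_bp must be positive")
  for (cls in c("S", "L")) {
    p <- cfg$class_params[[cls]]
    if (is.null(p)) stop("class_params must contain entries 'S' and 'L'")
    if (p$length_median_bp <= 0 || p$length_sd_bp < 0) {
      stop("class ", cls, ": lengths must be positive")
    }
    for (f in c("variant2_mean", "variant3_mean")) {
      if (p[[f]] <= 0 || p[[f]] >= 1) stop("class ", cls, ": ", f, " must be in (0, 1)")
    }
    if (p$variant2_mean + p$variant3_mean >= 1) {
      stop("class ", cls, ": variant2_mean + variant3_mean must be < 1")
    }
    if (p$tract_run_scale < 1) stop("class ", cls, ": tract_run_scale must be >= 1")
  }
  invisible(cfg)
}

# Split a unit count into run lengths with mean `scale` (geometric); scale 1
# forces runs of length 1.
run_lengths <- function(count, scale) {
  if (count == 0L) return(integer(0))
  if (scale <= 1) return(rep(1L, count))
  lens <- integer(0)
  while (sum(lens) < count) {
    lens <- c(lens, 1L + stats::rgeom(max(8L, ceiling(count / scale)), 1 / scale))
  }
  cum <- cumsum(lens)
  k <- which(cum >= count)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cum[k] - count)
  lens[lens > 0L]
}

# Order runs so no two adjacent runs share a variant (round-robin fill over
# odd then even positions, most frequent variant first). Used when runs must
# stay maximal, i.e. tract_run_scale == 1.
arrange_runs_strict <- function(run_vars) {
  n <- length(run_vars)
  if (n <= 1L) return(run_vars)
  tab <- sort(table(run_vars), decreasing = TRUE)
  if (as.integer(tab[1L]) > ceiling(n / 2)) {
    warning("run composition too skewed for a no-adjacency arrangement")
    return(sample(run_vars))
  }
  ordered <- unlist(lapply(names(tab), function(v) rep(v, tab[[v]])),
                    use.names = FALSE)
  out <- character(n)
  out[c(seq(1L, n, by = 2L), seq(2L, n, by = 2L))] <- ordered
  if (is.numeric(run_vars)) out <- as.numeric(out)
  out
}

#' Simulate one repeat allele
#'
#' Draws an interior length from the class-conditional truncated normal
#' (minimum `min_length_bp`, rounded to a whole number of 30-bp units), fixes
#' per-allele variant-2/variant-3 composition targets drawn from the class
#' means/SDs, allocates exact unit counts to those targets, splits each
#' variant's units into runs of geometric mean length `tract_run_scale`, and
#' shuffles the runs. Long-class alleles therefore carry longer perfect repeat
#' tracts by construction.
#'
#' @param class_label `"S"` or `"L"`.
#' @param config A [sim_config()].
#' @param catalog A `variant_catalog` from [generate_catalog()].
#' @param allele_id Identifier stored on the returned allele.
#' @return A `tract_allele` (see [decompose_tract()]) with truth metadata
#'   `meta$class` and `meta$target_props`.
#' @export
simulate_allele <- function(class_label, config, catalog,
                            allele_id = "sim_allele") {
  if (!class_label %in% c("S", "L")) stop("class_label must be 'S' or 'L'")
  p <- config$class_params[[class_label]]

  bp <- -Inf
  while (bp < config$min_length_bp) {
    bp <- stats::rnorm(1L, p$length_median_bp, p$length_sd_bp)
  }
  n_units <- max(10L, as.integer(round(bp / UNIT_BP)))

  clamp <- function(x, lo = 1e-3, hi = 0.95) min(max(x, lo), hi)
  p2 <- clamp(stats::rnorm(1L, p$variant2_mean, p$variant2_sd))
  p3 <- clamp(stats::rnorm(1L, p$variant3_mean, p$variant3_sd))
  p1 <- clamp(stats::rnorm(1L, p$variant1_mean, 0.02))
  if (p1 + p2 + p3 > 0.98) p1 <- 0.98 - p2 - p3

  c2 <- as.integer(round(p2 * n_units))
  c3 <- as.integer(round(p3 * n_units))
  c1 <- as.integer(round(p1 * n_units))
  rest <- n_units - c1 - c2 - c3
  if (rest < 0L) { c1 <- c1 + rest; rest <- 0L }

  extra_ids <- catalog$variant_id[catalog$variant_id > 3L]
  counts <- c(`1` = c1, `2` = c2, `3` = c3)
  if (rest > 0L && length(extra_ids) > 0L) {
    anchor <- unit_variants[[if (class_label == "S") "2" else "3"]]
    d <- hamming_to(catalog$sequence[catalog$variant_id > 3L], anchor)
    # rare units descend mostly from the class anchor: single-base neighbours
    # of the anchor get the full bias, two-base neighbours a damped one
    w <- catalog$cohort_count[catalog$variant_id > 3L] *
      ifelse(d == 1L, config$neighbor_bias,
             ifelse(d == 2L, sqrt(config$neighbor_bias), 1))
    extra_counts <- as.integer(stats::rmultinom(1L, rest, w))
    names(extra_counts) <- as.character(extra_ids)
    counts <- c(counts, extra_counts[extra_counts > 0L])
  } else if (rest > 0L) {
    counts["1"] <- counts["1"] + rest
  }
  counts <- counts[counts > 0L]

  runs <- do.call(rbind, lapply(names(counts), function(v) {
    ls <- run_lengths(counts[[v]], p$tract_run_scale)
    data.frame(var = rep(v, length(ls)), len = ls, stringsAsFactors = FALSE)
  }))
  if (p$tract_run_scale <= 1) {
    ord_vars <- arrange_runs_strict(runs$var)
    runs <- data.frame(var = ord_vars, len = 1L, stringsAsFactors = FALSE)
  } else {
    runs <- runs[sample.int(nrow(runs)), , drop = FALSE]
  }

  ids <- as.integer(rep(runs$var, runs$len))
  units <- catalog$sequence[match(ids, catalog$variant_id)]
  new_tract_allele(
    allele_id = allele_id,
    units = units,
    unit_ids = ids,
    flank5 = FLANK5_DEFAULT,
    flank3 = FLANK3_DEFAULT,
    residual = "",
    meta = list(class = class_label,
                target_props = c(v1 = p1, v2 = p2, v3 = p3))
  )
}

#' Simulate a diploid cohort under Hardy-Weinberg equilibrium
#'
#' Each individual draws two allele classes independently with L-class
#' frequency `long_allele_freq`. One SNP (the tag) is placed in LD with the L
#' indicator at approximately `tag_snp_r2` by making every L haplotype carry
#' the tag allele and adding just enough S-haplotype carriers; the remaining
#' SNPs are drawn independently per haplotype.
#'
#' @param config A [sim_config()].
#' @param alleles `"full"` to simulate unit-level alleles for every haplotype,
#'   or `"labels"` to generate class labels, SNPs and genotypes only (fast
#'   path for genotype-level studies).
#' @return A list of class `vntr_cohort` with elements `config`, `catalog`
#'   (NULL in labels mode), `individuals` (data frame: `id`, `class_h1`,
#'   `class_h2`, `genotype`, `dosage`), `alleles` (named list of
#'   `tract_allele`), `hap_long` (logical per haplotype), `snps` (0/1 matrix,
#'   haplotypes x sites) and `tag_index`.
#' @export
simulate_cohort <- function(config, alleles = c("full", "labels")) {
  alleles <- match.arg(alleles)
  validate_sim_config(config)
  q <- config$long_allele_freq
  if (q == 0 && config$tag_snp_r2 == 1) {
    stop("invalid configuration: tag_snp_r2 = 1 is impossible when long_allele_freq = 0")
  }
  set.seed(config$seed)
  catalog <- if (alleles == "full") {
    generate_catalog(seed = sample.int(.Machine$integer.max, 1L),
                     n_variants = config$n_catalog_variants)
  } else NULL

  n <- config$n_individuals
  ids <- sprintf("I%04d", seq_len(n))
  hap_long <- stats::rbinom(2L * n, 1L, q) == 1L
  names(hap_long) <- paste0(rep(ids, each = 2L), "_h", rep(1:2, n))
  cls <- ifelse(hap_long, "L", "S")
  class_h1 <- cls[seq(1L, 2L * n, by = 2L)]
  class_h2 <- cls[seq(2L, 2L * n, by = 2L)]
  dosage <- (class_h1 == "L") + (class_h2 == "L")
  individuals <- data.frame(
    id = ids, class_h1 = class_h1, class_h2 = class_h2,
    genotype = c("S/S", "S/L", "L/L")[dosage + 1L],
    dosage = dosage, stringsAsFactors = FALSE
  )

  snps <- matrix(0L, nrow = 2L * n, ncol = config$n_snps,
                 dimnames = list(names(hap_long),
                                 sprintf("snp%03d", seq_len(config$n_snps))))
  tag_index <- NA_integer_
  if (config$n_snps > 0L) {
    tag_index <- sample.int(config$n_snps, 1L)
    for (j in seq_len(config$n_snps)) {
      if (j == tag_index) next
      maf <- stats::runif(1L, 0.05, 0.5)
      snps[, j] <- stats::rbinom(2L * n, 1L, maf)
    }
    t <- config$tag_snp_r2
    tag <- as.integer(hap_long)
    if (t < 1 && q > 0 && t > 0) {
      pB <- q / (t * (1 - q) + q)
      extra <- round(pB * 2L * n) - sum(tag)
      s_idx <- which(!hap_long)
      if (extra > 0L && length(s_idx) > 0L) {
        tag[sample(s_idx, min(extra, length(s_idx)))] <- 1L
      }
    } else if (t == 0 && q > 0) {
      tag <- stats::rbinom(2L * n, 1L, max(q, 0.1))
    }
    snps[, tag_index] <- tag
  }

  allele_list <- list()
  if (alleles == "full") {
    allele_list <- vector("list", 2L * n)
    names(allele_list) <- names(hap_long)
    for (k in seq_len(2L * n)) {
      allele_list[[k]] <- simulate_allele(cls[k], config, catalog,
                                          allele_id = names(hap_long)[k])
    }
  }

  structure(list(config = config, catalog = catalog,
                 individuals = individuals, alleles = allele_list,
                 hap_long = hap_long, snps = snps, tag_index = tag_index),
            class = "vntr_cohort")
}

#' @export
print.vntr_cohort <- function(x, ...) {
  cat("Synthetic diploid cohort:", nrow(x$individuals), "individuals;",
      sum(x$hap_long), "L haplotypes;",
      length(x$alleles), "simulated alleles\n")
  print(table(x$individuals$genotype))
  invisible(x)
}

#' A four-generation, 23-member pedigree structure
#'
#' A pedigree with six founders (twelve founder haplotypes), mirroring the
#' deep multi-generation family design used for germline-stability analysis:
#' two founder couples, a second generation of five, two third-generation
#' marry-in founders, and seven fourth-generation children.
#'
#' @return A data frame with columns `member`, `father`, `mother` (NA for
#'   founders), topologically ordered.
#' @export
four_generation_pedigree <- function() {
  data.frame(
    member = c("F1", "F2", "F3", "F4",
               "P1", "P2", "P3", "P4", "P5",
               "K1", "K2", "K3", "K4", "K5", "M1", "M2",
               "Q1", "Q2", "Q3", "Q4", "Q5", "Q6", "Q7"),
    father = c(NA, NA, NA, NA,
               "F1", "F1", "F1", "F3", "F3",
               "P1", "P1", "P1", "P1", "P1", NA, NA,
               "M1", "M1", "M1", "M1", "M2", "M2", "M2"),
    mother = c(NA, NA, NA, NA,
               "F2", "F2", "F2", "F4", "F4",
               "P4", "P4", "P4", "P4", "P4", NA, NA,
               "K1", "K1", "K1", "K1", "K2", "K2", "K2"),
    stringsAsFactors = FALSE
  )
}

#' Simulate alleles through a pedigree with controllable de novo events
#'
#' Founders receive alleles drawn from the cohort class distribution; each
#' non-founder allele is a copy of one randomly chosen parental haplotype with
#' `Poisson(de_novo_per_transmission)` single-base substitutions applied at
#' distinct recorded interior positions. Length-changing events (single-unit
#' insertion/deletion) can be enabled via `length_event_rate`.
#'
#' @param config A [sim_config()].
#' @param structure Pedigree data frame (`member`, `father`, `mother`), parents
#'   listed before children; see [four_generation_pedigree()].
#' @param length_event_rate Expected Poisson count of single-unit
#'   insertions/deletions per transmission (default 0).
#' @return A list of class `vntr_pedigree`: `structure`, `alleles` (named
#'   `member_h1`/`member_h2`), `catalog`, `truth` (data frame per non-founder
#'   haplotype: donor allele, substitution count and positions, length-change
#'   count), `founder_labels` (named letters per founder haplotype).
#' @export
simulate_pedigree <- function(config, structure = four_generation_pedigree(),
                              length_event_rate = 0) {
  validate_sim_config(config)
  set.seed(config$seed)
  catalog <- generate_catalog(seed = sample.int(.Machine$integer.max, 1L),
                              n_variants = config$n_catalog_variants)
  members <- structure$member
  if (anyDuplicated(members)) stop("duplicate pedigree members")
  seen <- character(0)
  for (i in seq_along(members)) {
    for (par in c(structure$father[i], structure$mother[i])) {
      if (!is.na(par) && !par %in% seen) {
        stop("ordering error: member '", members[i],
             "' listed before parent '", par, "'")
      }
    }
    if (xor(is.na(structure$father[i]), is.na(structure$mother[i]))) {
      stop("non-founder '", members[i], "' must have two parents")
    }
    seen <- c(seen, members[i])
  }

  q <- config$long_allele_freq
  alleles <- list()
  truth <- list()
  founder_haps <- character(0)
  for (i in seq_along(members)) {
    m <- members[i]
    is_founder <- is.na(structure$father[i])
    for (h in 1:2) {
      hap_name <- paste0(m, "_h", h)
      if (is_founder) {
        cls <- if (stats::rbinom(1L, 1L, q) == 1L) "L" else "S"
        alleles[[hap_name]] <- simulate_allele(cls, config, catalog, hap_name)
        founder_haps <- c(founder_haps, hap_name)
      } else {
        par <- if (h == 1L) structure$father[i] else structure$mother[i]
        donor <- paste0(par, "_h", sample.int(2L, 1L))
        src <- alleles[[donor]]
        units <- src$units
        n_sub <- stats::rpois(1L, config$de_novo_per_transmission)
        n_len <- if (length_event_rate > 0) stats::rpois(1L, length_event_rate) else 0L
        interior_len <- length(units) * UNIT_BP
        n_sub <- min(n_sub, interior_len)
        pos <- if (n_sub > 0L) sort(sample.int(interior_len, n_sub)) else integer(0)
        for (p in pos) {
          ui <- (p - 1L) %/% UNIT_BP + 1L
          off <- (p - 1L) %% UNIT_BP + 1L
          old <- substr(units[ui], off, off)
          substr(units[ui], off, off) <- sample(setdiff(DNA_BASES, old), 1L)
        }
        if (n_len > 0L) {
          for (e in seq_len(n_len)) {
            if (stats::runif(1L) < 0.5 && length(units) > 1L) {
              units <- units[-sample.int(length(units), 1L)]
            } else {
              at <- sample.int(length(units), 1L)
              units <- append(units, units[at], after = at)
            }
          }
        }
        ids <- match(units, catalog$sequence)
        ids <- catalog$variant_id[ids]
        alleles[[hap_name]] <- new_tract_allele(
          allele_id = hap_name, units = units, unit_ids = ids,
          flank5 = src$flank5, flank3 = src$flank3, residual = "",
          meta = list(class = src$meta$class)
        )
        truth[[hap_name]] <- data.frame(
          child_hap = hap_name, donor = donor, n_substitutions = n_sub,
          positions = I(list(pos)), n_length_events = n_len,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  founder_labels <- stats::setNames(LETTERS[seq_along(founder_haps)], founder_haps)
  structure(list(structure = structure, alleles = alleles, catalog = catalog,
                 truth = do.call(rbind, truth),
                 founder_labels = founder_labels),
            class = "vntr_pedigree")
}

new_read_set <- function(reads, total_reads_in_sample) {
  stopifnot(total_reads_in_sample >= length(reads))
  structure(list(reads = reads,
                 total_reads_in_sample = total_reads_in_sample),
            class = "read_set")
}

#' Simulate short reads over an individual's repeat locus
#'
#' Reads are sampled uniformly across each haplotype sequence (5' flank +
#' interior + 3' flank) at `coverage_x` diploid depth, with independent
#' per-base substitution errors, and about half the reads reverse-complemented
#' to emulate strand sampling. The genome-wide total read count implied by
#' `genome_size_bp` is recorded for depth normalization.
#'
#' @param individual_alleles List of `tract_allele` objects (one per
#'   haplotype, typically two).
#' @param config A [sim_config()].
#' @return A `read_set`: `reads` (character vector of locus reads) and
#'   `total_reads_in_sample`.
#' @export
simulate_reads <- function(individual_alleles, config) {
  validate_sim_config(config)
  rl <- config$read_length_bp
  n_hap <- length(individual_alleles)
  reads <- character(0)
  for (al in individual_alleles) {
    seq_full <- paste0(al$flank5, allele_interior(al), al$flank3)
    len <- nchar(seq_full)
    if (len < rl) next
    n_reads <- stats::rpois(1L, config$coverage_x / n_hap * len / rl)
    if (n_reads == 0L) next
    starts <- sample.int(len - rl + 1L, n_reads, replace = TRUE)
    r <- substring(seq_full, starts, starts + rl - 1L)
    reads <- c(reads, r)
  }
  if (config$per_base_error > 0 && length(reads) > 0L) {
    n_err <- stats::rbinom(length(reads), rl, config$per_base_error)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(rl, n_err[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
      }
    }
  }
  if (length(reads) > 0L) {
    flip <- stats::runif(length(reads)) < 0.5
    if (any(flip)) {
      reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
    }
  }
  total <- max(length(reads),
               round(config$coverage_x * config$genome_size_bp / rl))
  new_read_set(reads, total)
}

#' Simulate an expression matrix with a dosage-linked target gene
#'
#' The first gene's expression is `baseline + expression_effect * dosage +
#' covariate effects + noise`; all other genes are covariate effects plus
#' noise only. Covariates are standard-normal with fixed moderate effects and
#' are returned for adjustment.
#'
#' @param cohort A `vntr_cohort` (provides the L-allele dosage truth).
#' @param config A [sim_config()].
#' @return A list of class `expression_sim`: `expr` (genes x subjects matrix),
#'   `covariates` (subjects x covariates data frame), `target_gene`, `effect`.
#' @export
simulate_expression <- function(cohort, config = cohort$config) {
  n <- nrow(cohort$individuals)
  g <- config$n_genes
  k <- config$n_covariates
  gene_ids <- sprintf("G%03d", seq_len(g))
  covariates <- if (k > 0L) {
    as.data.frame(matrix(stats::rnorm(n * k), nrow = n,
                         dimnames = list(cohort$individuals$id,
                                         paste0("cov", seq_len(k)))))
  } else data.frame(row.names = cohort$individuals$id)
  gamma <- if (k > 0L) seq(0.5, by = -0.2, length.out = k) else numeric(0)
  cov_part <- if (k > 0L) as.matrix(covariates) %*% gamma else matrix(0, n, 1L)
  expr <- matrix(stats::rnorm(g * n, sd = config$expression_noise_sd),
                 nrow = g, dimnames = list(gene_ids, cohort$individuals$id))
  expr <- expr + matrix(rep(as.numeric(cov_part), each = g), nrow = g)
  expr[1L, ] <- expr[1L, ] + config$expression_effect * cohort$individuals$dosage
  structure(list(expr = expr, covariates = covariates,
                 target_gene = gene_ids[1L], effect = config$expression_effect),
            class = "expression_sim")
}
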