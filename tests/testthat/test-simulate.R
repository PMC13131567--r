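cfg_default <- sim_config(seed = 11)
cat_default <- generate_catalog(1, 50)

test_that("configuration invariants are enforced", {
  expect_error(sim_config(long_allele_freq = 1.5), "long_allele_freq")
  expect_error(sim_config(read_length_bp = 29), "repeat unit")
  cp <- default_class_params(); cp$S$variant2_mean <- 0.8; cp$S$variant3_mean <- 0.3
  expect_error(sim_config(class_params = cp), "must be < 1")
  expect_error(
    simulate_cohort(sim_config(long_allele_freq = 0, tag_snp_r2 = 1)),
    "impossible")
})

test_that("allele interiors are unit multiples and decomposition inverts generation", {
  set.seed(5)
  for (cls in c("S", "L")) {
    a <- simulate_allele(cls, small_sim_config(), cat_default)
    expect_identical(a$interior_length_bp %% 30L, 0L)
    d <- decompose_tract(allele_interior(a), cat_default)
    expect_identical(d$units, a$units)
    expect_identical(d$unit_ids, a$unit_ids)
  }
})

test_that("class composition converges to the configured means", {
  set.seed(7)
  n_rep <- 1500
  p3_S <- replicate(n_rep, {
    a <- simulate_allele("S", small_sim_config(), cat_default)
    mean(a$unit_ids == 3, na.rm = TRUE)
  })
  se <- sd(p3_S) / sqrt(n_rep)
  expect_lt(abs(mean(p3_S) - 0.1076), 3 * se + 1e-3)
  p3_L <- replicate(300, {
    a <- simulate_allele("L", small_sim_config(), cat_default)
    mean(a$unit_ids == 3, na.rm = TRUE)
  })
  expect_lt(abs(mean(p3_L) - 0.2894), 3 * sd(p3_L) / sqrt(300) + 1e-3)
  # the 0.2 boundary is ~9 class SDs from the L mean: essentially always above
  expect_true(all(p3_L > 0.2))
})

test_that("unit run scale of 1 forces tracts of single units", {
  cp <- default_class_params()
  cp$S$tract_run_scale <- 1
  cfg <- sim_config(seed = 2, class_params = cp)
  set.seed(3)
  a <- simulate_allele("S", cfg, cat_default)
  expect_identical(max(find_perfect_tracts(a)$run_length), 1L)
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  cfg <- small_sim_config(seed = 21, n_individuals = 5, long_allele_freq = 0.2)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$alleles, c2$alleles)
  expect_identical(c1$snps, c2$snps)
  c3 <- simulate_cohort(small_sim_config(seed = 22, n_individuals = 5,
                                         long_allele_freq = 0.2))
  expect_false(identical(c1$snps, c3$snps))
})

test_that("cohorts respect Hardy-Weinberg carrier frequencies", {
  set.seed(77)
  q <- 0.031
  carrier_frac <- replicate(40, {
    cfg <- sim_config(seed = sample.int(1e6, 1), n_individuals = 400,
                      long_allele_freq = q, n_snps = 2)
    co <- simulate_cohort(cfg, alleles = "labels")
    mean(co$individuals$dosage > 0)
  })
  expected <- 1 - (1 - q)^2
  se <- sd(carrier_frac) / sqrt(length(carrier_frac))
  expect_lt(abs(mean(carrier_frac) - expected), 3 * se)
})

test_that("boundary cohorts behave: no long alleles at frequency zero", {
  cfg <- sim_config(seed = 4, n_individuals = 30, long_allele_freq = 0,
                    tag_snp_r2 = 0.5, n_snps = 3)
  co <- simulate_cohort(cfg, alleles = "labels")
  expect_true(all(co$individuals$genotype == "S/S"))
  expect_false(any(co$hap_long))
})

test_that("a perfectly tagging SNP reproduces the long-allele indicator", {
  cfg <- small_sim_config(seed = 8, n_individuals = 120,
                          long_allele_freq = 0.15, tag_snp_r2 = 1)
  co <- simulate_cohort(cfg, alleles = "labels")
  expect_identical(as.logical(co$snps[, co$tag_index]), unname(co$hap_long))
})

test_that("pedigree transmissions copy alleles and apply Poisson de novo events", {
  cfg0 <- small_sim_config(seed = 31, de_novo_per_transmission = 0)
  ped <- simulate_pedigree(cfg0)
  for (k in seq_len(nrow(ped$truth))) {
    child <- ped$alleles[[ped$truth$child_hap[k]]]
    donor <- ped$alleles[[ped$truth$donor[k]]]
    expect_identical(allele_interior(child), allele_interior(donor))
  }
  # mean induced events matches lambda
  cfg2 <- small_sim_config(seed = 32, de_novo_per_transmission = 2)
  events <- unlist(lapply(1:8, function(i) {
    cfg2$seed <- 32L + i
    simulate_pedigree(cfg2)$truth$n_substitutions
  }))
  se <- sd(events) / sqrt(length(events))
  expect_lt(abs(mean(events) - 2), 3 * se)
  # ordering validation
  bad <- data.frame(member = c("kid", "dad", "mom"),
                    father = c("dad", NA, NA), mother = c("mom", NA, NA),
                    stringsAsFactors = FALSE)
  expect_error(simulate_pedigree(cfg0, bad), "ordering error")
})

test_that("the bundled four-generation pedigree has 23 members and 6 founders", {
  st <- four_generation_pedigree()
  expect_identical(nrow(st), 23L)
  expect_identical(sum(is.na(st$father)), 6L)   # 12 founder haplotypes
  ped <- simulate_pedigree(small_sim_config(seed = 9), st)
  expect_identical(length(ped$founder_labels), 12L)
  expect_identical(unname(ped$founder_labels), LETTERS[1:12])
})

test_that("read simulation respects coverage and error settings", {
  cfg <- small_sim_config(seed = 41, per_base_error = 0, coverage_x = 40,
                          read_length_bp = 100)
  set.seed(41)
  a1 <- simulate_allele("S", cfg, cat_default, "h1")
  a2 <- simulate_allele("S", cfg, cat_default, "h2")
  rs <- simulate_reads(list(a1, a2), cfg)
  expect_s3_class(rs, "read_set")
  expect_true(all(nchar(rs$reads) == 100L))
  # diploid convention: each haplotype is sampled at coverage_x / 2
  len <- a1$interior_length_bp + a2$interior_length_bp + 4 * 60
  expected <- 40 / 2 * len / 100
  expect_lt(abs(length(rs$reads) - expected) / expected, 0.2)
  cfg0 <- small_sim_config(seed = 42, coverage_x = 0)
  rs0 <- simulate_reads(list(a1, a2), cfg0)
  expect_identical(length(rs0$reads), 0L)
})

test_that("noiseless expression recovers the configured effect exactly", {
  cfg <- sim_config(seed = 51, n_individuals = 60, long_allele_freq = 0.3,
                    expression_noise_sd = 1e-12, n_covariates = 0,
                    expression_effect = -1.5, n_genes = 4)
  co <- simulate_cohort(cfg, alleles = "labels")
  ex <- simulate_expression(co, cfg)
  scan <- association_scan(ex, co$individuals$dosage)
  expect_equal(scan$estimate[scan$gene == ex$target_gene], -1.5,
               tolerance = 1e-6)
})
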