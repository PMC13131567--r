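test_that("genotype coding counts long alleles and upgrades via haplotypes", {
  df <- data.frame(id = c("a", "b", "c"),
                   class_h1 = c("S", "S", "L"),
                   class_h2 = c("S", "L", "L"),
                   stringsAsFactors = FALSE)
  gc <- code_genotype(df)
  expect_identical(gc$dosage, c(0L, 1L, 2L))
  expect_identical(gc$label, c("S/S", "S/L", "L/L"))
  carriers <- c(a = "S/S", b = "carrier", c = "carrier")
  tags <- rbind(a = c(FALSE, FALSE), b = c(TRUE, FALSE), c = c(TRUE, TRUE))
  gc2 <- code_genotype(carriers, tag_haplotypes = tags)
  expect_identical(gc2$dosage, c(0L, 1L, 2L))
  # mean dosage ~ 2q in an HWE cohort
  co <- simulate_cohort(sim_config(seed = 71, n_individuals = 800,
                                   long_allele_freq = 0.1, n_snps = 2),
                        alleles = "labels")
  gc3 <- code_genotype(co$individuals)
  expect_lt(abs(mean(gc3$dosage) - 0.2), 3 * sd(gc3$dosage) / sqrt(800))
})

test_that("haplotype r-squared matches hand-computed LD", {
  # perfect LD
  a <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(ld_r2(a, a), 1)
  # 2x2 haplotype table AB=40, Ab=10, aB=10, ab=40:
  # D = 0.4 - 0.5 * 0.5 = 0.15; r2 = 0.15^2 / 0.5^4 = 0.36
  A <- rep(c(1, 1, 0, 0), times = c(40, 10, 10, 40))
  B <- rep(c(1, 0, 1, 0), times = c(40, 10, 10, 40))
  expect_equal(ld_r2(A, B), 0.36)
  expect_equal(ld_r2(A, B), stats::cor(A, B)^2)
  # allele relabeling leaves r2 unchanged
  expect_equal(ld_r2(1 - A, B), 0.36)
  expect_warning(r <- ld_r2(rep(1, 10), rep(c(0, 1), 5)), "monomorphic")
  expect_true(is.na(r))
})

test_that("r-squared equals squared Pearson correlation on random haplotypes", {
  set.seed(72)
  for (i in 1:25) {
    a <- rbinom(200, 1, runif(1, 0.1, 0.9))
    b <- rbinom(200, 1, runif(1, 0.1, 0.9))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(ld_r2(a, b), cor(a, b)^2, tolerance = 1e-12)
    expect_gte(ld_r2(a, b), 0)
    expect_lte(ld_r2(a, b), 1)
  }
})

test_that("an independent SNP shows near-zero r-squared at large n", {
  set.seed(73)
  r2 <- replicate(50, {
    a <- rbinom(10000, 1, 0.3)
    b <- rbinom(10000, 1, 0.4)
    ld_r2(a, b)
  })
  expect_gte(mean(r2 < 0.01), 0.99)
})

test_that("Hardy-Weinberg homozygote expectations follow the closed form", {
  expect_equal(hwe_expected_homozygotes(10, 100), 100 * 0.05^2)
  expect_equal(hwe_expected_homozygotes(0, 100), 0)
  expect_error(hwe_expected_homozygotes(5, 0), "invalid input")
  expect_error(hwe_expected_homozygotes(300, 100), "exceed")
})

test_that("association scan matches lm gene by gene", {
  set.seed(74)
  n <- 80
  dosage <- rbinom(n, 2, 0.2)
  covs <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  expr <- matrix(rnorm(5 * n), nrow = 5,
                 dimnames = list(paste0("g", 1:5), NULL))
  expr[2, ] <- expr[2, ] + 0.8 * dosage
  scan <- association_scan(expr, dosage, covs)
  for (g in 1:5) {
    fit <- summary(lm(expr[g, ] ~ dosage + covs$c1 + covs$c2))
    expect_equal(scan$estimate[g], fit$coefficients["dosage", 1],
                 tolerance = 1e-10)
    expect_equal(scan$std_error[g], fit$coefficients["dosage", 2],
                 tolerance = 1e-10)
    expect_equal(scan$p_value[g], fit$coefficients["dosage", 4],
                 tolerance = 1e-10)
  }
  expect_true(all(scan$p_bonferroni >= scan$p_value))
})

test_that("association scan flags collinear covariates by name", {
  set.seed(75)
  n <- 40
  dosage <- rbinom(n, 2, 0.3)
  covs <- data.frame(ok = rnorm(n), dup = dosage * 2)
  expr <- matrix(rnorm(3 * n), nrow = 3,
                 dimnames = list(paste0("g", 1:3), NULL))
  expect_error(association_scan(expr, dosage, covs), "dup")
})

test_that("noiseless expression gives the exact coefficient", {
  n <- 50
  dosage <- rep(0:2, length.out = n)
  expr <- matrix(2 * dosage, nrow = 1, dimnames = list("g1", NULL))
  scan <- association_scan(expr, dosage)
  expect_equal(scan$estimate, 2, tolerance = 1e-9)
  expect_lt(scan$p_value, 1e-12)
})
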