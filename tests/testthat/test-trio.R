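test_that("alignment parameter invariants are enforced", {
  p <- alignment_params()
  expect_equal(p$match, 1)
  expect_equal(p$gap_extend, -0.5)
  expect_error(alignment_params(match = -1), "match")
  expect_error(alignment_params(gap_open = -0.1, gap_extend = -3),
               "gap_open <= gap_extend")
})

test_that("global alignment reproduces known affine-gap scores", {
  expect_equal(global_align("ACGTACGT", "ACGTACGT")$score, 8)
  expect_equal(global_align("ACGT", "ACGA")$score, 2)   # 3 matches - 1 mismatch
  expect_equal(global_align("ACGT", "ACG")$score, 0)    # 3 matches - 3 gap
  # a gap of length k costs 3 + 0.5 (k - 1)
  expect_equal(global_align("AAAATTTT", "AAAA")$score, 4 - 3 - 0.5 * 3)
})

test_that("alignment scores are symmetric and maximal on self", {
  set.seed(23)
  for (i in 1:20) {
    a <- random_dna(sample(5:60, 1))
    b <- random_dna(sample(5:60, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_equal(global_align(a, a)$score, nchar(a))
  }
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment scores match an explicit Gotoh oracle on random pairs", {
  set.seed(24)
  for (i in 1:60) {
    a <- random_dna(sample(1:60, 1))
    b <- random_dna(sample(1:60, 1))
    expect_equal(global_align(a, b)$score, gotoh_score(a, b),
                 info = paste(a, b))
  }
})

test_that("inheritance assignment picks the max-scoring parental allele", {
  set.seed(25)
  parents <- lapply(1:4, function(i) random_dna(300))
  child <- parents[[3]]
  call <- assign_inheritance(child, parents)
  expect_identical(call$inherited_index, 3L)
  expect_equal(call$alignment_score, 300)
  expect_false(call$tie_flag)
  expect_identical(call$de_novo_count, 0L)
  # one substitution: score drops by 2, still assigned to the donor
  child2 <- parents[[2]]
  substr(child2, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                      substr(child2, 150, 150))[1]
  call2 <- assign_inheritance(child2, parents)
  expect_identical(call2$inherited_index, 2L)
  expect_equal(call2$alignment_score, 298)
  expect_identical(call2$de_novo_substitutions, 1L)
  expect_error(assign_inheritance(child, parents[1:3]), "invalid trio")
})

test_that("ties are flagged and resolved to the lowest parent index", {
  set.seed(26)
  dup <- random_dna(200)
  parents <- list(random_dna(200), dup, dup, random_dna(200))
  call <- assign_inheritance(dup, parents)
  expect_true(call$tie_flag)
  expect_identical(call$inherited_index, 2L)
})

test_that("de novo counting separates substitutions from length changes", {
  set.seed(27)
  a <- random_dna(600)
  expect_identical(count_de_novo(a, a)$total, 0L)
  b <- a
  substr(b, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(a, 100, 100))[1]
  cd <- count_de_novo(b, a)
  expect_identical(cd$substitutions, 1L)
  expect_identical(cd$length_changes, 0L)
  # one 30-base deletion is one length-change event
  del <- paste0(substr(a, 1, 300), substr(a, 331, 600))
  cd2 <- count_de_novo(del, a)
  expect_identical(cd2$length_changes, 1L)
  expect_identical(cd2$substitutions, 0L)
})

test_that("founder labels propagate through a pedigree without de novo events", {
  cfg <- small_sim_config(seed = 61, de_novo_per_transmission = 0)
  st <- data.frame(member = c("F", "M", "C1", "C2", "G"),
                   father = c(NA, NA, "F", "F", NA),
                   mother = c(NA, NA, "M", "M", NA),
                   stringsAsFactors = FALSE)
  ped <- simulate_pedigree(cfg, st)
  labels <- trace_founder_alleles(ped)
  expect_identical(sum(labels$founder), 6L)          # F, M and G haplotypes
  expect_identical(labels$label[labels$founder], LETTERS[1:6])
  expect_true(all(labels$de_novo_count[!labels$founder] == 0L))
  # each child label equals the truth donor's label
  lab_of <- stats::setNames(labels$label, labels$hap)
  for (k in seq_len(nrow(ped$truth))) {
    expect_identical(lab_of[[ped$truth$child_hap[k]]],
                     lab_of[[ped$truth$donor[k]]])
  }
  # founder-only pedigree keeps founder labels untouched
  st0 <- st[1:2, ]
  ped0 <- simulate_pedigree(cfg, st0)
  lab0 <- trace_founder_alleles(ped0)
  expect_identical(lab0$label, LETTERS[1:4])
})
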