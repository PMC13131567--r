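v1 <- unit_variants[["1"]]; v2 <- unit_variants[["2"]]; v3 <- unit_variants[["3"]]
catalog3 <- generate_catalog(1, 3)

test_that("locate_tract extracts the interior between the flank anchors", {
  interior <- strrep(v1, 4)
  hap <- paste0(FLANK5_DEFAULT, interior, FLANK3_DEFAULT)
  loc <- locate_tract(hap, FLANK5_DEFAULT, FLANK3_DEFAULT)
  expect_identical(loc$interior, interior)
  expect_identical(loc$start, nchar(FLANK5_DEFAULT))
  expect_identical(loc$end, nchar(FLANK5_DEFAULT) + 120L)
  expect_identical(loc$strand, "+")
})

test_that("locate_tract is strand-symmetric", {
  interior <- paste0(strrep(v1, 3), v2)
  hap <- paste0(FLANK5_DEFAULT, interior, FLANK3_DEFAULT)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hap)))
  loc <- locate_tract(rc, FLANK5_DEFAULT, FLANK3_DEFAULT)
  expect_identical(loc$interior, interior)
  expect_identical(loc$strand, "-")
})

test_that("locate_tract rejects decoys, missing loci and ambiguous flanks", {
  set.seed(1)
  decoy_interior <- random_dna(120)
  # confirm by construction that no probe occurs in the decoy interior
  expect_false(any(vapply(unit_variants, grepl, TRUE, x = decoy_interior,
                          fixed = TRUE)))
  decoy <- paste0(FLANK5_DEFAULT, decoy_interior, FLANK3_DEFAULT)
  expect_error(locate_tract(decoy, FLANK5_DEFAULT, FLANK3_DEFAULT),
               "decoy-locus")
  expect_error(locate_tract(random_dna(500), FLANK5_DEFAULT, FLANK3_DEFAULT),
               "locus-absent")
  double <- paste0(FLANK5_DEFAULT, strrep(v1, 2), FLANK5_DEFAULT,
                   strrep(v1, 2), FLANK3_DEFAULT)
  expect_error(locate_tract(double, FLANK5_DEFAULT, FLANK3_DEFAULT),
               "ambiguity")
})

test_that("decomposition chunks in fixed 30-base frame with residual", {
  d <- decompose_tract(paste0(v1, v1, v2), catalog3)
  expect_identical(d$unit_ids, c(1L, 1L, 2L))
  expect_identical(d$residual, "")
  # 95 bases: 3 units + 5 residual bases, excluded from counts
  set.seed(2)
  tail5 <- substr(random_dna(5), 1, 5)
  d95 <- decompose_tract(paste0(v1, v2, v3, tail5), catalog3)
  expect_identical(length(d95$units), 3L)
  expect_identical(nchar(d95$residual), 5L)
  expect_identical(d95$interior_length_bp, 95L)
  # a single unit decomposes to itself
  d1 <- decompose_tract(v1, catalog3)
  expect_identical(d1$units, v1)
  expect_error(decompose_tract(substr(v1, 1, 29), catalog3), "no-units")
})

test_that("decomposition round-trips arbitrary interiors", {
  set.seed(3)
  for (i in 1:20) {
    interior <- random_dna(sample(30:400, 1))
    d <- suppressWarnings(decompose_tract(interior, catalog3))
    expect_identical(paste0(paste(d$units, collapse = ""), d$residual),
                     interior)
  }
})

test_that("uncatalogued units are reported, not dropped", {
  odd <- strrep("A", 30)
  expect_warning(d <- decompose_tract(paste0(v1, odd), catalog3),
                 "uncatalogued")
  expect_identical(d$unit_ids, c(1L, NA_integer_))
})

test_that("unit profiles follow the counting rules", {
  units <- c(v1, v1, v2, v2, v2)
  p <- profile_from_units(units, catalog3)
  expect_equal(p$table$proportion[p$table$variant_id == 1], 0.4)
  expect_equal(p$table$proportion[p$table$variant_id == 2], 0.6)
  expect_equal(sum(p$table$proportion), 1, tolerance = 1e-9)
  expect_error(profile_from_units(rep(strrep("A", 30), 3), catalog3),
               "no-countable-units")
})

test_that("the within-5-of-variant-1 rule excludes variant 1 itself", {
  units <- c(v1, v1, v2, v3)
  p <- profile_from_units(units, catalog3, denominator_rule = "WITHIN5_OF_V1")
  expect_identical(p$counted_units, 2L)           # v2 and v3 only
  expect_equal(sum(p$table$proportion), 1, tolerance = 1e-9)
  expect_error(
    profile_from_units(c(v1, v1), catalog3, denominator_rule = "WITHIN5_OF_V1"),
    "no-countable-units")
})

test_that("read profiles count exact 30-mer windows in both orientations", {
  p <- profile_from_reads(v2, catalog3)
  expect_equal(variant_proportion(p, 2L), 1)
  # 59 bases: v1 complete, then 29 bases of v2 -> v2 not counted
  r59 <- paste0(v1, substr(v2, 1, 29))
  p59 <- profile_from_reads(r59, catalog3)
  expect_identical(p59$table$count[p59$table$variant_id == 1], 1L)
  expect_false(2L %in% p59$table$variant_id)
  # reverse-complemented read counts the same
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(v2)))
  prc <- profile_from_reads(rc, catalog3)
  expect_equal(variant_proportion(prc, 2L), 1)
  expect_error(profile_from_reads(strrep("A", 40), catalog3),
               "no-countable-units")
})

test_that("normalized depth is locus reads per million total", {
  rs <- structure(list(reads = rep("ACGT", 100), total_reads_in_sample = 1e6),
                  class = "read_set")
  expect_equal(normalized_depth(rs), 100)
  rs0 <- structure(list(reads = character(0), total_reads_in_sample = 1e6),
                   class = "read_set")
  expect_equal(normalized_depth(rs0), 0)
  rs_bad <- structure(list(reads = character(0), total_reads_in_sample = 0),
                      class = "read_set")
  expect_error(normalized_depth(rs_bad), "invalid input")
})
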