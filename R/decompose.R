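new_tract_allele <- function(allele_id, units, unit_ids, flank5, flank3,
                             residual = "", meta = list()) {
  stopifnot(length(units) == length(unit_ids), nchar(residual) < UNIT_BP)
  structure(list(allele_id = allele_id, units = units, unit_ids = unit_ids,
                 flank5 = flank5, flank3 = flank3, residual = residual,
                 interior_length_bp = length(units) * UNIT_BP + nchar(residual),
                 meta = meta),
            class = "tract_allele")
}

#' Interior sequence of a tract allele
#'
#' Concatenation of the allele's unit sequences and residual bases; inverts
#' [decompose_tract()] exactly.
#' @param allele A `tract_allele`.
#' @return A character scalar.
#' @export
allele_interior <- function(allele) {
  paste0(paste(allele$units, collapse = ""), allele$residual)
}

#' @export
print.tract_allele <- function(x, ...) {
  n_unc <- sum(is.na(x$unit_ids))
  cat("Tract allele '", x$allele_id, "': ", length(x$units), " units (",
      x$interior_length_bp, " bp interior", sep = "")
  if (nchar(x$residual) > 0L) cat(", ", nchar(x$residual), " residual bases", sep = "")
  if (n_unc > 0L) cat(", ", n_unc, " uncatalogued", sep = "")
  if (!is.null(x$meta$class)) cat("; class ", x$meta$class, sep = "")
  cat(")\n")
  invisible(x)
}

match_all <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Locate the repeat interior between its unique flanks
#'
#' Searches a haplotype sequence for exact anchors taken from the provided
#' flanks (the last `anchor_bp` bases of the 5' flank and the first
#' `anchor_bp` of the 3' flank), on both strands, and returns the sequence
#' strictly between them in 5'-flank to 3'-flank orientation. At least one of
#' the probe variants must occur in the interior, guarding against decoy loci
#' with coincidentally similar flanks.
#'
#' @param haplotype_seq Character scalar, the assembled haplotype.
#' @param flank5,flank3 Unique flanking sequences (non-empty).
#' @param probe_variants Character vector of 30-base unit sequences expected
#'   inside a genuine repeat interior (default: the top three variants).
#' @param anchor_bp Anchor length used for exact matching (default 20).
#' @return A list: `interior`, `start`, `end` (0-based half-open interior
#'   coordinates on the matched strand) and `strand` (`"+"` or `"-"`).
#' @export
locate_tract <- function(haplotype_seq, flank5, flank3,
                         probe_variants = unname(unit_variants),
                         anchor_bp = 20L) {
  if (!nzchar(flank5) || !nzchar(flank3)) stop("flanks must be non-empty")
  if (length(probe_variants) == 0L) stop("probe_variants must be non-empty")
  a5 <- substr(flank5, max(1L, nchar(flank5) - anchor_bp + 1L), nchar(flank5))
  a3 <- substr(flank3, 1L, min(anchor_bp, nchar(flank3)))

  try_strand <- function(seqs, strand) {
    h5 <- match_all(a5, seqs)
    h3 <- match_all(a3, seqs)
    if (length(h5) == 0L || length(h3) == 0L) return(NULL)
    if (length(h5) > 1L) {
      stop("ambiguity error: 5' flank anchor matches at positions ",
           paste(h5, collapse = ", "))
    }
    start <- h5[1L] + nchar(a5)           # 1-based first interior base
    h3 <- h3[h3 >= start]
    if (length(h3) == 0L) return(NULL)
    end <- h3[1L]                          # 1-based first base of 3' anchor
    interior <- substr(seqs, start, end - 1L)
    list(interior = interior, start = start - 1L, end = end - 1L,
         strand = strand)
  }
  res <- try_strand(haplotype_seq, "+")
  if (is.null(res)) {
    res <- try_strand(reverse_complement(haplotype_seq), "-")
  }
  if (is.null(res)) stop("locus-absent error: flank anchors not found on either strand")
  if (!any(vapply(probe_variants, function(p) grepl(p, res$interior, fixed = TRUE),
                  logical(1L)))) {
    stop("decoy-locus error: no probe variant occurs in the candidate interior")
  }
  res
}

#' Decompose a repeat interior into 30-bp units
#'
#' Chunks the interior into consecutive 30-base windows anchored at position
#' zero. Each unit is looked up in the catalog by exact match; units absent
#' from the catalog get `NA` IDs (uncatalogued) and a warning reports their
#' fraction. A trailing remainder shorter than 30 bases is stored as
#' `residual` and excluded from all counts.
#'
#' @param interior Character scalar, the repeat interior sequence.
#' @param catalog Optional `variant_catalog` for unit identification.
#' @param allele_id Identifier for the returned allele.
#' @param flank5,flank3 Flank sequences carried as metadata.
#' @return A `tract_allele`.
#' @export
decompose_tract <- function(interior, catalog = NULL, allele_id = "allele",
                            flank5 = "", flank3 = "") {
  len <- nchar(interior)
  if (len < UNIT_BP) stop("no-units error: interior shorter than one unit")
  n_units <- len %/% UNIT_BP
  starts <- (seq_len(n_units) - 1L) * UNIT_BP + 1L
  units <- substring(interior, starts, starts + UNIT_BP - 1L)
  residual <- if (len %% UNIT_BP > 0L) {
    substr(interior, n_units * UNIT_BP + 1L, len)
  } else ""
  ids <- if (!is.null(catalog)) {
    catalog$variant_id[match(units, catalog$sequence)]
  } else rep(NA_integer_, n_units)
  if (!is.null(catalog) && anyNA(ids)) {
    warning(sprintf("%.1f%% of units are uncatalogued (%d/%d)",
                    100 * mean(is.na(ids)), sum(is.na(ids)), n_units))
  }
  new_tract_allele(allele_id, units, ids, flank5, flank3, residual)
}

new_variant_profile <- function(subject_id, level, table, denominator_rule,
                                counted_units) {
  structure(list(subject_id = subject_id, level = level, table = table,
                 denominator_rule = denominator_rule,
                 counted_units = counted_units),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("Variant profile (", x$level, " '", x$subject_id, "'): ",
      x$counted_units, " counted units, rule ", x$denominator_rule, "\n", sep = "")
  top <- utils::head(x$table[order(-x$table$proportion), ], 5L)
  print.data.frame(top, row.names = FALSE)
  invisible(x)
}

#' Proportion of a given variant in a profile
#'
#' @param profile A `variant_profile`.
#' @param variant_id Catalog ID (default 3, the long-class marker variant).
#' @return The proportion (0 if the variant is absent from the profile).
#' @export
variant_proportion <- function(profile, variant_id = 3L) {
  i <- match(variant_id, profile$table$variant_id)
  if (is.na(i)) 0 else profile$table$proportion[i]
}

#' Variant-proportion profile from decomposed units
#'
#' Computes per-variant unit proportions for one allele or one individual
#' (both haplotypes pooled). Under `CATALOG_MATCHED` the denominator is the
#' units matching any catalog entry. Under `WITHIN5_OF_V1` the denominator is
#' the units within Hamming distance 5 of variant 1, with exact variant 1
#' excluded from numerator and denominator (the rare-variant convention of the
#' mutational-neighborhood analysis).
#'
#' @param units Character vector of 30-base unit sequences, or a
#'   `tract_allele`.
#' @param catalog A `variant_catalog`.
#' @param denominator_rule `"CATALOG_MATCHED"` or `"WITHIN5_OF_V1"`.
#' @param subject_id,level Profile identity metadata.
#' @return A `variant_profile`; its `table` has columns `variant_id` (NA for
#'   uncatalogued sequences under `WITHIN5_OF_V1`), `sequence`, `count`,
#'   `proportion` (summing to 1).
#' @export
profile_from_units <- function(units, catalog,
                               denominator_rule = c("CATALOG_MATCHED",
                                                    "WITHIN5_OF_V1"),
                               subject_id = "subject",
                               level = c("allele", "individual")) {
  denominator_rule <- match.arg(denominator_rule)
  level <- match.arg(level)
  if (inherits(units, "tract_allele")) units <- units$units
  if (length(units) == 0L) stop("no-countable-units error: empty unit set")
  if (denominator_rule == "CATALOG_MATCHED") {
    ids <- catalog$variant_id[match(units, catalog$sequence)]
    keep <- !is.na(ids)
    if (!any(keep)) stop("no-countable-units error: no unit matches the catalog")
    tab <- table(ids[keep])
    out <- data.frame(
      variant_id = as.integer(names(tab)),
      sequence = catalog$sequence[match(as.integer(names(tab)),
                                        catalog$variant_id)],
      count = as.integer(tab), stringsAsFactors = FALSE
    )
  } else {
    v1 <- unit_variants[["1"]]
    d <- hamming_to(units, v1)
    keep <- d <= 5L & d > 0L
    if (!any(keep)) stop("no-countable-units error: denominator empty under WITHIN5_OF_V1")
    tab <- table(units[keep])
    out <- data.frame(
      variant_id = catalog$variant_id[match(names(tab), catalog$sequence)],
      sequence = names(tab), count = as.integer(tab), stringsAsFactors = FALSE
    )
  }
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$proportion <- out$count / sum(out$count)
  rownames(out) <- NULL
  new_variant_profile(subject_id, level, out, denominator_rule, sum(out$count))
}

#' Variant-proportion profile from short reads
#'
#' Counts every exact occurrence of each catalog sequence within the reads:
#' all 30-base windows of each read are tested, on both read orientations.
#' Proportions are over total catalog-sequence occurrences.
#'
#' @param reads A `read_set` (see [simulate_reads()]) or character vector.
#' @param catalog A `variant_catalog`.
#' @param subject_id Profile identity.
#' @return A `variant_profile` at the individual level.
#' @export
profile_from_reads <- function(reads, catalog, subject_id = "subject") {
  rd <- if (inherits(reads, "read_set")) reads$reads else reads
  if (length(rd) == 0L) stop("no-countable-units error: no reads")
  ss <- Biostrings::DNAStringSet(rd)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(catalog$sequence))
  counts <- rowSums(Biostrings::vcountPDict(pd, ss)) +
    rowSums(Biostrings::vcountPDict(pd, Biostrings::reverseComplement(ss)))
  keep <- counts > 0L
  if (!any(keep)) stop("no-countable-units error: no catalog sequence occurs in the reads")
  out <- data.frame(variant_id = catalog$variant_id[keep],
                    sequence = catalog$sequence[keep],
                    count = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$proportion <- out$count / sum(out$count)
  rownames(out) <- NULL
  new_variant_profile(subject_id, "individual", out, "CATALOG_MATCHED",
                      sum(out$count))
}

#' Normalized locus read depth
#'
#' Reads overlapping the locus divided by the sample's total read count,
#' scaled by one million -- the depth proxy for repeat length from short
#' reads.
#'
#' @param reads A `read_set`.
#' @return Locus reads per million total reads.
#' @export
normalized_depth <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  if (reads$total_reads_in_sample <= 0) stop("invalid input: zero total reads")
  length(reads$reads) / reads$total_reads_in_sample * 1e6
}
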