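#' Canonical 30-bp repeat unit variants
#'
#' The three most prevalent 30-bp repeat unit sequences at the locus, in
#' prevalence order. Variant 2 and variant 3 each differ from variant 1 by a
#' single base; variants 2 and 3 differ from each other at two positions.
#'
#' @format A named character vector of three 30-base sequences
#'   (names `"1"`, `"2"`, `"3"`).
#' @export
unit_variants <- c(
  "1" = "GACCCTGACCTGACTAGTTTACAATCACAC",
  "2" = "GATCCTGACCTGACTAGTTTACAATCACAC",
  "3" = "GACCCTGACCTGACTAGTTTACAACCACAC"
)

#' Unit size of the repeat in base pairs
#' @export
UNIT_BP <- 30L

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between equal-length sequences
#'
#' Number of mismatching positions. No alignment is attempted: comparing
#' sequences of unequal length is an error, because a frame-shifted unit is
#' not a unit variant.
#'
#' @param u,v Character scalars of equal length (typically 30-base units).
#' @return Integer count of mismatching positions.
#' @examples
#' hamming(unit_variants[["1"]], unit_variants[["2"]])  # 1
#' @export
hamming <- function(u, v) {
  stopifnot(is.character(u), is.character(v), length(u) == 1L, length(v) == 1L)
  if (nchar(u) != nchar(v)) {
    stop("hamming() requires equal-length sequences (got ", nchar(u), " and ",
         nchar(v), " bases); no alignment fallback is provided")
  }
  sum(utf8ToInt(u) != utf8ToInt(v))
}

# Vectorised Hamming distance of many units against one reference of the same
# width. Units are assumed pre-validated (equal nchar); used in hot paths.
hamming_to <- function(units, ref) {
  if (length(units) == 0L) return(integer(0))
  w <- nchar(ref)
  if (any(nchar(units) != w)) stop("all units must have width ", w)
  refi <- utf8ToInt(ref)
  m <- matrix(utf8ToInt(paste(units, collapse = "")), nrow = w)
  as.integer(colSums(m != refi))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

new_variant_catalog <- function(df) {
  stopifnot(all(c("variant_id", "sequence", "cohort_count",
                  "mean_per_individual") %in% names(df)))
  structure(df, class = c("variant_catalog", "data.frame"))
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("Variant catalog:", nrow(x), "distinct", UNIT_BP, "bp units\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

# Mutate `k` random positions of a 30-mer to different bases.
mutate_kmer <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic prevalence-ranked variant catalog
#'
#' Produces a catalog whose first three entries are the canonical variant 1, 2
#' and 3 sequences (see [unit_variants]) and whose remaining entries are
#' mutational neighbours of those three: each is derived by substituting 1-5
#' random bases (weighted toward single-base changes), mirroring the way rare
#' unit variants arise from common ones. Assigned prevalences decrease with
#' rank so that catalog IDs are a strict prevalence ranking.
#'
#' @param seed Integer seed for reproducibility.
#' @param n_variants Total number of catalog entries (must be >= 3).
#' @param n_individuals Nominal cohort size used to express the per-individual
#'   mean count column.
#' @return A `variant_catalog` data frame with columns `variant_id`,
#'   `sequence`, `cohort_count`, `mean_per_individual` and `parent_id` (the
#'   canonical variant each extra entry was derived from; `NA` for IDs 1-3).
#' @export
generate_catalog <- function(seed, n_variants = 50L, n_individuals = 2490L) {
  if (n_variants < 3L) {
    stop("invalid configuration: a catalog needs at least the 3 canonical variants")
  }
  set.seed(seed)
  seqs <- unname(unit_variants)
  parents <- c(NA_integer_, NA_integer_, NA_integer_)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs) assign(s, TRUE, envir = seen)
  while (length(seqs) < n_variants) {
    parent <- sample.int(3L, 1L, prob = c(0.4, 0.3, 0.3))
    k <- sample.int(5L, 1L, prob = c(0.55, 0.2, 0.12, 0.08, 0.05))
    cand <- mutate_kmer(seqs[parent], k)
    if (!exists(cand, envir = seen, inherits = FALSE)) {
      assign(cand, TRUE, envir = seen)
      seqs <- c(seqs, cand)
      parents <- c(parents, parent)
    }
  }
  # Unit-share targets: ~31% variant 1, ~17% variant 2, ~11% variant 3 with a
  # geometric tail, scaled to strictly decreasing integer cohort counts.
  n <- length(seqs)
  share <- c(0.31, 0.17, 0.11, 0.41 * 0.75^(seq_len(n - 3L)) * 0.25 /
               (1 - 0.75^(n - 3L)))[seq_len(n)]
  total_units <- n_individuals * 200L
  counts <- pmax(1L, as.integer(round(share * total_units)))
  counts <- counts - (seq_len(n) - 1L)        # enforce strict decrease on ties
  counts <- pmax(counts, rev(seq_len(n)))
  counts <- cummin(counts)
  new_variant_catalog(data.frame(
    variant_id = seq_len(n),
    sequence = seqs,
    cohort_count = counts,
    mean_per_individual = counts / n_individuals,
    parent_id = parents,
    stringsAsFactors = FALSE
  ))
}

#' Build a prevalence-ranked variant catalog from cohort unit counts
#'
#' Counts distinct unit sequences across a cohort and retains those seen on
#' average more than `min_mean_per_individual` times per individual. IDs are
#' assigned by decreasing cohort count, ties broken lexicographically by
#' sequence.
#'
#' @param cohort_units A list with one character vector of unit sequences per
#'   individual (both haplotypes pooled).
#' @param min_mean_per_individual Retention threshold on the mean per-individual
#'   count (strict inequality); default 0.2.
#' @return A `variant_catalog`.
#' @export
build_catalog <- function(cohort_units, min_mean_per_individual = 0.2) {
  if (!is.list(cohort_units) || length(cohort_units) == 0L) {
    stop("invalid input: cohort_units must be a non-empty list of unit vectors")
  }
  n_ind <- length(cohort_units)
  all_units <- unlist(cohort_units, use.names = FALSE)
  if (length(all_units) == 0L) stop("invalid input: no units in cohort")
  widths <- nchar(all_units)
  if (any(widths != UNIT_BP)) {
    stop("all units must be ", UNIT_BP, " bases wide")
  }
  tab <- table(all_units)
  keep <- (as.numeric(tab) / n_ind) > min_mean_per_individual
  tab <- tab[keep]
  if (length(tab) == 0L) stop("no unit sequence passes the retention threshold")
  ord <- order(-as.numeric(tab), names(tab))
  tab <- tab[ord]
  new_variant_catalog(data.frame(
    variant_id = seq_along(tab),
    sequence = names(tab),
    cohort_count = as.integer(tab),
    mean_per_individual = as.numeric(tab) / n_ind,
    parent_id = NA_integer_,
    stringsAsFactors = FALSE
  ))
}
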