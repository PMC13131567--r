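#' Alignment scoring parameters
#'
#' Global affine-gap scoring: match +1, mismatch -1, a gap of length k costs
#' `gap_open + (k - 1) * gap_extend` (the first gap position pays
#' `gap_open`). Defaults are the standard parameter set for this analysis:
#' match 1, mismatch -1, open -3, extend -0.5.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (gap scores are
#'   negative).
#' @return A validated list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -3,
                             gap_extend = -0.5) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("need gap_open <= gap_extend <= 0")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh global alignment of two nucleotide sequences under
#' the convention that a gap of length k costs `gap_open + (k-1) *
#' gap_extend`. Backed by Biostrings' C implementation.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param params An [alignment_params()].
#' @return A list of class `global_alignment`: `score`, `aligned_a`,
#'   `aligned_b` (gapped strings of equal width), `n_mismatch` (mismatch
#'   columns), `n_gap_segments` (contiguous gap runs across both rows).
#' @export
global_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("invalid input: empty sequence")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch,
                                                  baseOnly = TRUE)
  # Biostrings charges gapOpening + gapExtension * k for a gap of length k;
  # gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend
  # reproduces gap_open + (k-1) * gap_extend.
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sub,
    gapOpening = -(params$gap_open - params$gap_extend),
    gapExtension = -params$gap_extend
  )
  pat <- as.character(Biostrings::alignedPattern(pa))
  sbj <- as.character(Biostrings::alignedSubject(pa))
  cp <- strsplit(pat, "", fixed = TRUE)[[1L]]
  cs <- strsplit(sbj, "", fixed = TRUE)[[1L]]
  gap <- cp == "-" | cs == "-"
  n_mismatch <- sum(!gap & cp != cs)
  n_gap_segments <- sum(diff(c(FALSE, gap)) == 1L)
  structure(list(score = Biostrings::score(pa), aligned_a = pat,
                 aligned_b = sbj, n_mismatch = n_mismatch,
                 n_gap_segments = n_gap_segments, params = params),
            class = "global_alignment")
}

#' Assign a child allele to its inherited parental allele
#'
#' Aligns the child interior sequence against each of the four parental
#' interiors and selects the maximum alignment score. Ties set `tie_flag` and
#' resolve to the lowest-indexed parental allele -- never silently.
#'
#' @param child_allele A `tract_allele` or interior sequence string.
#' @param parental_alleles List of exactly four `tract_allele`s or strings
#'   (father h1, father h2, mother h1, mother h2 by convention).
#' @param params An [alignment_params()].
#' @return A list of class `trio_call`: `child_allele_id`,
#'   `inherited_parent_allele_id`, `inherited_index`, `alignment_score`,
#'   `tie_flag`, `de_novo_substitutions`, `de_novo_length_changes`,
#'   `de_novo_count` (events: mismatch columns plus gap segments), `scores`
#'   (all four).
#' @export
assign_inheritance <- function(child_allele, parental_alleles,
                               params = alignment_params()) {
  if (length(parental_alleles) != 4L) {
    stop("invalid trio: exactly four parental alleles are required")
  }
  as_seq <- function(x) if (inherits(x, "tract_allele")) allele_interior(x) else x
  as_id <- function(x, d) if (inherits(x, "tract_allele")) x$allele_id else d
  child_seq <- as_seq(child_allele)
  alns <- lapply(parental_alleles, function(p) {
    global_align(child_seq, as_seq(p), params)
  })
  scores <- vapply(alns, `[[`, 0, "score")
  best <- which(scores == max(scores))
  tie <- length(best) > 1L
  k <- best[1L]
  structure(list(
    child_allele_id = as_id(child_allele, "child"),
    inherited_parent_allele_id = as_id(parental_alleles[[k]],
                                       paste0("parent", k)),
    inherited_index = k,
    alignment_score = scores[k],
    tie_flag = tie,
    de_novo_substitutions = alns[[k]]$n_mismatch,
    de_novo_length_changes = alns[[k]]$n_gap_segments,
    de_novo_count = alns[[k]]$n_mismatch + alns[[k]]$n_gap_segments,
    scores = scores),
    class = "trio_call")
}

#' @export
print.trio_call <- function(x, ...) {
  cat("Trio call: child '", x$child_allele_id, "' inherits '",
      x$inherited_parent_allele_id, "' (score ", x$alignment_score,
      if (x$tie_flag) ", TIE" else "", ")\n", sep = "")
  cat("  de novo: ", x$de_novo_substitutions, " substitution(s), ",
      x$de_novo_length_changes, " length change(s)\n", sep = "")
  invisible(x)
}

#' Count de novo mutations between a child allele and its inherited allele
#'
#' Aligns the two sequences globally and counts mismatch columns
#' (substitution events) and contiguous gap segments (length-change events,
#' one event per segment regardless of gap width).
#'
#' @param child_allele,inherited_allele `tract_allele`s or strings.
#' @param params An [alignment_params()].
#' @return A list: `substitutions`, `length_changes`, `total`.
#' @export
count_de_novo <- function(child_allele, inherited_allele,
                          params = alignment_params()) {
  as_seq <- function(x) if (inherits(x, "tract_allele")) allele_interior(x) else x
  a <- as_seq(child_allele); b <- as_seq(inherited_allele)
  if (identical(a, b)) {
    return(list(substitutions = 0L, length_changes = 0L, total = 0L))
  }
  aln <- global_align(a, b, params)
  list(substitutions = aln$n_mismatch, length_changes = aln$n_gap_segments,
       total = aln$n_mismatch + aln$n_gap_segments)
}

#' Trace founder allele labels through a pedigree
#'
#' Founder haplotypes receive letter labels (A, B, C, ...) in pedigree order;
#' each non-founder haplotype is assigned by aligning it against its parents'
#' four alleles ([assign_inheritance()]) and inherits the matched allele's
#' label. Members introduced by marriage (founders in later generations) get
#' fresh labels.
#'
#' @param pedigree A `vntr_pedigree` from [simulate_pedigree()], or a list
#'   with `structure` (member/father/mother data frame) and `alleles` (named
#'   `member_h1`/`member_h2` list).
#' @param params An [alignment_params()].
#' @return A data frame per haplotype: `member`, `hap`, `label`, `founder`,
#'   `tie_flag`, `de_novo_count`.
#' @export
trace_founder_alleles <- function(pedigree, params = alignment_params()) {
  st <- pedigree$structure
  alleles <- pedigree$alleles
  labels <- list()
  next_label <- 1L
  rows <- list()
  for (i in seq_len(nrow(st))) {
    m <- st$member[i]
    is_founder <- is.na(st$father[i])
    for (h in 1:2) {
      hap <- paste0(m, "_h", h)
      if (is_founder) {
        labels[[hap]] <- LETTERS[next_label]
        next_label <- next_label + 1L
        rows[[hap]] <- data.frame(member = m, hap = hap, label = labels[[hap]],
                                  founder = TRUE, tie_flag = FALSE,
                                  de_novo_count = 0L, stringsAsFactors = FALSE)
      } else {
        four <- c(paste0(st$father[i], "_h", 1:2),
                  paste0(st$mother[i], "_h", 1:2))
        call <- assign_inheritance(alleles[[hap]], alleles[four], params)
        donor_hap <- four[call$inherited_index]
        lab <- labels[[donor_hap]]
        if (is.null(lab)) {
          stop("pedigree-inconsistency error: no label for donor '",
               donor_hap, "'")
        }
        labels[[hap]] <- lab
        rows[[hap]] <- data.frame(member = m, hap = hap, label = lab,
                                  founder = FALSE, tie_flag = call$tie_flag,
                                  de_novo_count = call$de_novo_count,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
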