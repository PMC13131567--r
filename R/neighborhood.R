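#' 1-bp mutational-neighborhood profile of an individual's units
#'
#' Quantifies, among an individual's repeat units close to variant 1, the
#' fraction that are single-base neighbours of variant 2 and of variant 3.
#' The denominator is all units within Hamming distance 5 of variant 1,
#' excluding exact variant 1 (which is one base from both variant 2 and
#' variant 3 and would swamp both numerators). Numerators count units at
#' Hamming distance exactly 1 from the target variant, so the target variant
#' itself is not its own neighbour. With a `stratum_threshold`, numerators
#' are restricted to unit sequences whose cohort-wide frequency is below the
#' threshold (rare-variant strata).
#'
#' @param units Character vector of an individual's unit sequences (both
#'   haplotypes pooled), or a `tract_allele`.
#' @param stratum_threshold Optional cohort-frequency upper bound (e.g. 0.01);
#'   requires `cohort_freqs`.
#' @param cohort_freqs Named numeric vector of cohort-wide unit-sequence
#'   frequencies (fraction of all counted units), as from
#'   [cohort_unit_frequencies()].
#' @param subject_id Identity metadata.
#' @return A list of class `neighborhood_profile`: `denominator_units`,
#'   `frac_1bp_from_v2`, `frac_1bp_from_v3`, `stratum`.
#' @export
neighborhood_profile <- function(units, stratum_threshold = NULL,
                                 cohort_freqs = NULL, subject_id = "subject") {
  if (inherits(units, "tract_allele")) units <- units$units
  if (length(units) == 0L) stop("undefined-profile error: no units")
  v1 <- unit_variants[["1"]]; v2 <- unit_variants[["2"]]; v3 <- unit_variants[["3"]]
  d1 <- hamming_to(units, v1)
  denom_mask <- d1 <= 5L & d1 > 0L
  denom <- sum(denom_mask)
  if (denom == 0L) stop("undefined-profile error: empty denominator (only variant 1 present?)")
  u <- units[denom_mask]
  near2 <- hamming_to(u, v2) == 1L
  near3 <- hamming_to(u, v3) == 1L
  if (!is.null(stratum_threshold)) {
    if (is.null(cohort_freqs)) {
      stop("cohort_freqs are required when stratum_threshold is set")
    }
    f <- cohort_freqs[u]
    f[is.na(f)] <- 0
    rare <- f < stratum_threshold
    near2 <- near2 & rare
    near3 <- near3 & rare
  }
  structure(list(subject_id = subject_id, denominator_units = denom,
                 frac_1bp_from_v2 = sum(near2) / denom,
                 frac_1bp_from_v3 = sum(near3) / denom,
                 stratum = if (is.null(stratum_threshold)) "all"
                           else paste0("freq<", stratum_threshold)),
            class = "neighborhood_profile")
}

#' Cohort-wide unit-sequence frequencies
#'
#' @param cohort_units List with one unit-sequence vector per individual.
#' @return Named numeric vector: fraction of all counted units per distinct
#'   sequence.
#' @export
cohort_unit_frequencies <- function(cohort_units) {
  all_units <- unlist(cohort_units, use.names = FALSE)
  tab <- table(all_units)
  stats::setNames(as.numeric(tab) / length(all_units), names(tab))
}

#' Compare mutational-neighborhood fractions between carriers and non-carriers
#'
#' Two-sided Wilcoxon rank-sum tests of `frac_1bp_from_v2` and
#' `frac_1bp_from_v3` between S/S individuals and carriers (S/L or L/L), with
#' the direction of the difference reported.
#'
#' @param profiles List of `neighborhood_profile` objects.
#' @param genotype_labels Character vector parallel to `profiles`: `"S/S"`
#'   for non-carriers, anything else (e.g. `"S/L"`, `"L/L"`, `"carrier"`)
#'   for carriers.
#' @return A list of class `neighborhood_comparison`: per-fraction
#'   `test_result`s, group medians and directions.
#' @export
compare_carriers <- function(profiles, genotype_labels) {
  stopifnot(length(profiles) == length(genotype_labels))
  is_carrier <- genotype_labels != "S/S"
  if (!any(is_carrier) || all(is_carrier)) {
    stop("invalid comparison: both genotype groups must be non-empty")
  }
  f2 <- vapply(profiles, `[[`, 0, "frac_1bp_from_v2")
  f3 <- vapply(profiles, `[[`, 0, "frac_1bp_from_v3")
  cmp <- function(x) {
    res <- wilcoxon_rank_sum(x[!is_carrier], x[is_carrier])
    list(test = res,
         median_SS = stats::median(x[!is_carrier]),
         median_carrier = stats::median(x[is_carrier]),
         direction = if (stats::median(x[!is_carrier]) >
                         stats::median(x[is_carrier])) "higher_in_SS"
                     else "higher_in_carriers")
  }
  structure(list(v2 = cmp(f2), v3 = cmp(f3),
                 n_SS = sum(!is_carrier), n_carrier = sum(is_carrier),
                 stratum = profiles[[1L]]$stratum),
            class = "neighborhood_comparison")
}

#' @export
print.neighborhood_comparison <- function(x, ...) {
  cat("Mutational-neighborhood enrichment (stratum ", x$stratum, "): ",
      x$n_SS, " S/S vs ", x$n_carrier, " carriers\n", sep = "")
  cat(sprintf("  1 bp from variant 2: p = %.3g (%s)\n",
              x$v2$test$p_value, x$v2$direction))
  cat(sprintf("  1 bp from variant 3: p = %.3g (%s)\n",
              x$v3$test$p_value, x$v3$direction))
  invisible(x)
}
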