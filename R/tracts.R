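#' Find maximal perfect repeat tracts in an allele
#'
#' A perfect repeat tract is a maximal run of consecutive units with identical
#' 30-base sequence. Comparison is by full sequence, so uncatalogued units
#' form a run only when byte-identical; the tracts partition the unit array.
#'
#' @param allele A `tract_allele`, or a character vector of unit sequences.
#' @return A data frame with one row per tract: `variant_sequence`,
#'   `variant_id` (NA when uncatalogued or no catalog), `start_index`
#'   (0-based unit offset), `run_length`.
#' @export
find_perfect_tracts <- function(allele) {
  if (inherits(allele, "tract_allele")) {
    units <- allele$units
    ids <- allele$unit_ids
  } else {
    units <- allele
    ids <- rep(NA_integer_, length(units))
  }
  if (length(units) == 0L) stop("no-units error: empty allele")
  r <- rle(units)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # 0-based
  data.frame(variant_sequence = r$values,
             variant_id = ids[starts + 1L],
             start_index = as.integer(starts),
             run_length = as.integer(r$lengths),
             stringsAsFactors = FALSE)
}

#' Summarize perfect repeat tracts of an allele
#'
#' @param allele A `tract_allele` or unit-sequence vector.
#' @param min_units Minimum run length for a tract to qualify (default 5).
#' @return A list of class `tract_summary`: `n_tracts_ge_min`,
#'   `proportion_in_tracts_ge_min` (fraction of units inside qualifying
#'   tracts), `longest_run`, `total_units`, `min_units`.
#' @export
summarize_tracts <- function(allele, min_units = 5L) {
  if (min_units < 1L) stop("invalid configuration: min_units must be >= 1")
  tr <- find_perfect_tracts(allele)
  qual <- tr$run_length >= min_units
  structure(list(
    n_tracts_ge_min = sum(qual),
    proportion_in_tracts_ge_min = sum(tr$run_length[qual]) / sum(tr$run_length),
    longest_run = max(tr$run_length),
    total_units = sum(tr$run_length),
    min_units = as.integer(min_units)),
    class = "tract_summary")
}

#' Compare perfect-tract statistics between allele classes
#'
#' Pools per-tract run lengths within each class and compares the two pooled
#' distributions by the two-sample Kolmogorov-Smirnov test; per-allele counts
#' and proportions of qualifying tracts (>= `min_units` units) are compared
#' by Wilcoxon rank-sum tests.
#'
#' @param S_alleles,L_alleles Lists of `tract_allele` objects (or unit-vector
#'   lists) for the short and long classes.
#' @param min_units Qualifying tract size (default 5).
#' @return A list of class `tract_comparison`: `ks_lengths`,
#'   `wilcoxon_n_tracts`, `wilcoxon_proportion` (each a `test_result`), plus
#'   per-class summary data frames.
#' @export
compare_tract_classes <- function(S_alleles, L_alleles, min_units = 5L) {
  if (length(S_alleles) == 0L || length(L_alleles) == 0L) {
    stop("invalid comparison: both classes must be non-empty")
  }
  pull <- function(alleles, cls) {
    tr <- lapply(alleles, find_perfect_tracts)
    sm <- lapply(alleles, summarize_tracts, min_units = min_units)
    list(lengths = unlist(lapply(tr, `[[`, "run_length"), use.names = FALSE),
         summary = data.frame(
           class = cls,
           n_tracts_ge_min = vapply(sm, `[[`, 0, "n_tracts_ge_min"),
           proportion_in_tracts_ge_min =
             vapply(sm, `[[`, 0, "proportion_in_tracts_ge_min"),
           longest_run = vapply(sm, `[[`, 0, "longest_run")))
  }
  s <- pull(S_alleles, "S")
  l <- pull(L_alleles, "L")
  if (length(s$lengths) == 0L || length(l$lengths) == 0L) {
    stop("invalid comparison: a class has zero tracts")
  }
  structure(list(
    ks_lengths = ks_two_sample(s$lengths, l$lengths),
    wilcoxon_n_tracts = wilcoxon_rank_sum(s$summary$n_tracts_ge_min,
                                          l$summary$n_tracts_ge_min),
    wilcoxon_proportion = wilcoxon_rank_sum(s$summary$proportion_in_tracts_ge_min,
                                            l$summary$proportion_in_tracts_ge_min),
    summary_S = s$summary, summary_L = l$summary,
    min_units = as.integer(min_units)),
    class = "tract_comparison")
}

#' @export
print.tract_comparison <- function(x, ...) {
  cat("Perfect-tract comparison (qualifying tracts >=", x$min_units, "units)\n")
  cat(sprintf("  KS on pooled tract lengths: D = %.4f, p = %.3g\n",
              x$ks_lengths$statistic, x$ks_lengths$p_value))
  cat(sprintf("  Wilcoxon, tracts per allele: U = %.1f, p = %.3g\n",
              x$wilcoxon_n_tracts$statistic, x$wilcoxon_n_tracts$p_value))
  cat(sprintf("  Wilcoxon, proportion in tracts: U = %.1f, p = %.3g\n",
              x$wilcoxon_proportion$statistic, x$wilcoxon_proportion$p_value))
  invisible(x)
}
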