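new_test_result <- function(statistic, p_value, method, sidedness, n1, n2) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 sidedness = sidedness, n1 = n1, n2 = n2),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, " (", x$sidedness, "; n1 = ", x$n1, ", n2 = ", x$n2, "): ",
      "statistic = ", signif(x$statistic, 5), ", p = ", signif(x$p_value, 4),
      "\n", sep = "")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' asymptotic by default, with an exact option for small samples. Ties (as
#' with integer tract lengths) make the p-value conservative/approximate, as
#' usual for the KS test.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact `NULL` (exact when `n1 * n2 <= 10000` and there are no ties)
#'   or a logical.
#' @return A `test_result` (`method = "KS2"`, two-sided).
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("invalid input: empty sample")
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  new_test_result(unname(res$statistic), res$p.value, "KS2", "two.sided",
                  length(x), length(y))
}

# Exact two-sample Wilcoxon by enumeration of all C(n1+n2, n1) group
# assignments of the midranks; valid with ties.
wilcoxon_exact_perm <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- switch(alternative,
    two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9),
    greater   = mean(u_all >= u_obs - 1e-9),
    less      = mean(u_all <= u_obs + 1e-9))
  list(u = u_obs, p = p)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties. The p-value is exact by full permutation enumeration
#' when `n1 + n2 <= exact_max` (valid with ties), otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param sidedness `"two.sided"` (default), `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max Total-sample-size bound for the exact path (default 12).
#' @return A `test_result` (`method = "WilcoxonRankSum"`, statistic U in
#'   `[0, n1 n2]`).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              sidedness = c("two.sided", "greater", "less"),
                              exact_max = 12L) {
  sidedness <- match.arg(sidedness)
  if (length(x) == 0L || length(y) == 0L) stop("invalid input: empty sample")
  n1 <- length(x); n2 <- length(y)
  if (n1 + n2 <= exact_max) {
    res <- wilcoxon_exact_perm(x, y, sidedness)
    return(new_test_result(res$u, res$p, "WilcoxonRankSum", sidedness, n1, n2))
  }
  res <- suppressWarnings(stats::wilcox.test(x, y, alternative = sidedness,
                                             exact = FALSE, correct = TRUE))
  new_test_result(unname(res$statistic), res$p.value, "WilcoxonRankSum",
                  sidedness, n1, n2)
}

#' Bonferroni multiple-testing correction
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of tests (default `length(p_values)`).
#' @return A list: `adjusted` (`min(1, p * m)`), `significant` (logical,
#'   `adjusted < alpha`), `m`.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values))) {
    stop("invalid input: p-values must lie in (0, 1]")
  }
  adjusted <- if (m >= length(p_values)) {
    stats::p.adjust(p_values, method = "bonferroni", n = m)
  } else pmin(1, p_values * m)
  list(adjusted = adjusted, significant = adjusted < alpha, m = m)
}
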