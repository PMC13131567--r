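#' Assemble a profile matrix from variant profiles
#'
#' Builds the subjects x variants proportion matrix used by PCA and k-means.
#' Variants absent from a subject's profile get proportion 0, so rows still
#' sum to 1 over the union of observed variants.
#'
#' @param profiles List of `variant_profile` objects.
#' @return A numeric matrix (rows = subjects, columns = variant IDs as
#'   character names).
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  ids <- sort(unique(unlist(lapply(profiles, function(p) p$table$variant_id))))
  ids <- ids[!is.na(ids)]
  m <- matrix(0, nrow = length(profiles), ncol = length(ids),
              dimnames = list(vapply(profiles, function(p) p$subject_id, ""),
                              as.character(ids)))
  for (i in seq_along(profiles)) {
    tab <- profiles[[i]]$table
    tab <- tab[!is.na(tab$variant_id), , drop = FALSE]
    m[i, as.character(tab$variant_id)] <- tab$proportion
  }
  m
}

#' Principal component scores of a proportion matrix
#'
#' PCA of the column-mean-centered (unscaled) matrix. The sign of PC1 is
#' fixed so the loading of variant 3 is positive, making high PC1 correspond
#' to high variant-3 proportion; subsequent components get the same
#' variant-3-loading convention when that loading is nonzero.
#'
#' @param matrix Subjects x variants proportion matrix (see
#'   [profile_matrix()]).
#' @param n_components Number of components to return.
#' @return A list: `scores` (subjects x components), `loadings`,
#'   `explained_variance` (fractions).
#' @export
pca_scores <- function(matrix, n_components = 2L) {
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("PCA needs at least 2 subjects and 2 variants")
  }
  if (all(abs(sweep(matrix, 2L, colMeans(matrix))) < 1e-12)) {
    stop("degenerate-input error: zero total variance")
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  if ("3" %in% rownames(loadings)) {
    for (j in seq_len(k)) {
      l3 <- loadings["3", j]
      if (!is.na(l3) && l3 < 0) {
        loadings[, j] <- -loadings[, j]
        scores[, j] <- -scores[, j]
      }
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)])
}

#' Two-group k-means clustering of composition profiles
#'
#' k-means with k = 2 on the raw proportion matrix (neither PC scores nor
#' standardized columns), best of `n_restarts` random starts. The cluster
#' with the lower mean variant-3 proportion is always named `"major"`, the
#' other `"minor"`, removing label-permutation ambiguity.
#'
#' @param matrix Subjects x variants proportion matrix.
#' @param seed Integer seed.
#' @param n_restarts Number of random starts (default 25).
#' @return A list of class `cluster_assignment`: `labels` (named character,
#'   `"major"`/`"minor"`), `cluster_means_v3`, `pc1_scores`, `degenerate`
#'   flag, `tot_withinss`.
#' @export
cluster_two <- function(matrix, seed = 1L, n_restarts = 25L) {
  if (n_restarts < 1L) stop("invalid configuration: n_restarts must be >= 1")
  if (nrow(matrix) < 2L) stop("clustering needs at least 2 subjects")
  set.seed(seed)
  dup <- nrow(unique(matrix)) < 2L
  if (dup) {
    warning("degenerate clustering: all subjects identical; one empty cluster")
    labels <- stats::setNames(rep("major", nrow(matrix)), rownames(matrix))
    v3 <- if ("3" %in% colnames(matrix)) matrix[, "3"] else rep(0, nrow(matrix))
    return(structure(list(labels = labels,
                          cluster_means_v3 = c(major = mean(v3), minor = NA_real_),
                          pc1_scores = NULL, degenerate = TRUE,
                          tot_withinss = 0),
                     class = "cluster_assignment"))
  }
  km <- stats::kmeans(matrix, centers = 2L, nstart = n_restarts)
  v3 <- if ("3" %in% colnames(matrix)) matrix[, "3"] else rep(0, nrow(matrix))
  means_v3 <- tapply(v3, km$cluster, mean)
  major_cl <- as.integer(names(which.min(means_v3)))
  labels <- ifelse(km$cluster == major_cl, "major", "minor")
  names(labels) <- rownames(matrix)
  pc1 <- tryCatch(pca_scores(matrix, 1L)$scores[, 1L], error = function(e) NULL)
  structure(list(
    labels = labels,
    cluster_means_v3 = c(major = unname(means_v3[as.character(major_cl)]),
                         minor = unname(means_v3[setdiff(names(means_v3),
                                                         as.character(major_cl))])),
    pc1_scores = pc1, degenerate = FALSE, tot_withinss = km$tot.withinss),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Two-group composition clustering:\n")
  print(table(x$labels))
  cat("mean variant-3 proportion: major =",
      signif(x$cluster_means_v3[["major"]], 4),
      "; minor =", signif(x$cluster_means_v3[["minor"]], 4), "\n")
  invisible(x)
}

#' Classify an allele as short (S) or long (L) class
#'
#' An allele is long-class iff its variant-3 proportion strictly exceeds the
#' threshold (default 0.2); a proportion of exactly 0.2 is short-class.
#'
#' @param profile A `variant_profile`, or a numeric variant-3 proportion.
#' @param threshold Classification threshold (default 0.2).
#' @return `"S"` or `"L"`.
#' @export
classify_allele <- function(profile, threshold = 0.2) {
  p3 <- if (inherits(profile, "variant_profile")) {
    variant_proportion(profile, 3L)
  } else as.numeric(profile)
  if (p3 > threshold) "L" else "S"
}

#' Individual-level carrier genotype from a composition profile
#'
#' Individuals in the minor composition cluster (or, with threshold context,
#' with variant-3 proportion above the boundary) are carriers of at least one
#' long allele; the rest are S/S. Refinement of carriers to L/L homozygotes
#' requires haplotype evidence and is handled by [code_genotype()].
#'
#' @param profile A `variant_profile` at the individual level.
#' @param assignment_context Either a `cluster_assignment` containing the
#'   subject, or a numeric threshold on the variant-3 proportion.
#' @return `"S/S"` or `"carrier"`.
#' @export
genotype_from_individual_profile <- function(profile,
                                             assignment_context = 0.2) {
  if (inherits(assignment_context, "cluster_assignment")) {
    lab <- assignment_context$labels[[profile$subject_id]]
    if (is.null(lab) || is.na(lab)) stop("subject not present in cluster assignment")
    if (lab == "minor") "carrier" else "S/S"
  } else {
    if (variant_proportion(profile, 3L) > assignment_context) "carrier" else "S/S"
  }
}
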