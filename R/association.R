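#' Code the long allele as a biallelic genotype
#'
#' With allele-level classifications, dosage is simply the count of L
#' alleles. With only individual-level carrier status, carriers get dosage 1
#' unless haplotype evidence upgrades them to 2 (both phased haplotypes carry
#' the tagging haplotype).
#'
#' @param allele_classes Either a data frame with columns `class_h1`,
#'   `class_h2` (values `"S"`/`"L"`, rownames or `id` column as subject IDs),
#'   or a character vector of carrier labels (`"S/S"`/`"carrier"`) when only
#'   individual-level profiles exist.
#' @param tag_haplotypes Optional logical matrix (subjects x 2) of tag-SNP
#'   carriage per phased haplotype, used to upgrade carriers to L/L.
#' @return A data frame of class `genotype_coding`: `id`, `dosage` (0/1/2),
#'   `label` (`"S/S"`, `"S/L"`, `"L/L"`).
#' @export
code_genotype <- function(allele_classes, tag_haplotypes = NULL) {
  if (is.data.frame(allele_classes)) {
    ids <- if ("id" %in% names(allele_classes)) allele_classes$id
           else rownames(allele_classes)
    dosage <- (allele_classes$class_h1 == "L") + (allele_classes$class_h2 == "L")
  } else {
    ids <- names(allele_classes)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_along(allele_classes))
    dosage <- ifelse(allele_classes == "S/S", 0L, 1L)
    if (!is.null(tag_haplotypes)) {
      both_tag <- rowSums(tag_haplotypes) == 2L
      dosage[dosage == 1L & both_tag] <- 2L
    }
  }
  if (anyNA(dosage)) {
    warning("missing classification for ", sum(is.na(dosage)),
            " subject(s); excluded")
  }
  out <- data.frame(id = ids, dosage = as.integer(dosage),
                    label = c("S/S", "S/L", "L/L")[dosage + 1L],
                    stringsAsFactors = FALSE)
  structure(out[!is.na(out$dosage), , drop = FALSE],
            class = c("genotype_coding", "data.frame"))
}

#' Linkage disequilibrium r-squared between two haplotype indicators
#'
#' Computed over phased haplotypes: `r2 = D^2 / (pA (1-pA) pB (1-pB))` with
#' `D = pAB - pA pB`. Equals the squared Pearson correlation of the two
#' binary indicators and is invariant to allele relabeling at either locus.
#'
#' @param hap_a,hap_b Equal-length binary (0/1 or logical) vectors, one entry
#'   per haplotype.
#' @return r-squared in `[0, 1]`, or `NA` with a warning if either locus is
#'   monomorphic (undefined, not zero).
#' @export
ld_r2 <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b), length(hap_a) > 0L)
  a <- as.numeric(hap_a); b <- as.numeric(hap_b)
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    warning("undefined r2: monomorphic locus")
    return(NA_real_)
  }
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' LD scan of the long-allele indicator against all SNP sites
#'
#' @param hap_long Logical vector per haplotype (TRUE = long-class allele).
#' @param snps 0/1 haplotype-by-site matrix (as in a `vntr_cohort`).
#' @return Data frame: `site`, `r2` (NA where undefined).
#' @export
ld_scan <- function(hap_long, snps) {
  stopifnot(length(hap_long) == nrow(snps))
  r2 <- vapply(seq_len(ncol(snps)), function(j) {
    suppressWarnings(ld_r2(hap_long, snps[, j]))
  }, 0)
  data.frame(site = colnames(snps), r2 = r2, stringsAsFactors = FALSE)
}

#' Expected homozygote count under Hardy-Weinberg equilibrium
#'
#' @param allele_count_L Number of L alleles observed in the cohort.
#' @param n_subjects Number of diploid subjects.
#' @return `n_subjects * q^2` with `q = allele_count_L / (2 n_subjects)`.
#' @export
hwe_expected_homozygotes <- function(allele_count_L, n_subjects) {
  if (n_subjects <= 0L) stop("invalid input: n_subjects must be positive")
  if (allele_count_L > 2L * n_subjects) {
    stop("allele_count_L cannot exceed 2 * n_subjects")
  }
  q <- allele_count_L / (2 * n_subjects)
  n_subjects * q^2
}

#' Covariate-adjusted linear association scan over genes
#'
#' Per gene, ordinary least squares of expression on the predictor plus
#' covariates, a two-sided t-test on the predictor coefficient, and
#' Bonferroni correction over all genes tested. One QR decomposition of the
#' shared design is used for all genes (numerically identical to per-gene
#' `lm`).
#'
#' @param expression Genes x subjects numeric matrix (or an
#'   `expression_sim`).
#' @param predictor Numeric vector per subject: L-allele dosage, a variant
#'   proportion, or normalized read depth.
#' @param covariates Optional subjects x covariates data frame or matrix.
#' @param predictor_name Label stored in the result (default
#'   `"dosage"`).
#' @return A data frame of class `association_scan`: `gene`, `estimate`,
#'   `std_error`, `p_value`, `p_bonferroni`, `n`, `predictor`.
#' @export
association_scan <- function(expression, predictor, covariates = NULL,
                             predictor_name = "dosage") {
  if (inherits(expression, "expression_sim")) expression <- expression$expr
  n <- ncol(expression)
  stopifnot(length(predictor) == n)
  X <- cbind(`(Intercept)` = 1, predictor = predictor)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == n)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  p <- ncol(X)
  if (n - p < 3L) stop("fewer than 3 residual degrees of freedom")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficiency error: collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- t(expression)                      # subjects x genes
  XtX_inv <- chol2inv(chol(crossprod(X)))
  coefs <- XtX_inv %*% crossprod(X, Y)
  rownames(coefs) <- colnames(X)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  v_pred <- XtX_inv[2L, 2L]
  est <- coefs["predictor", ]
  se <- sqrt(sigma2 * v_pred)
  tval <- est / se
  # exactly-zero residual variance gives p = 0 numerically; keep p in (0, 1]
  pval <- pmax(2 * stats::pt(-abs(tval), df), .Machine$double.xmin)
  out <- data.frame(gene = rownames(expression), estimate = est,
                    std_error = se, p_value = pval,
                    p_bonferroni = bonferroni(pval)$adjusted,
                    n = n, predictor = predictor_name,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("association_scan", "data.frame"))
}
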