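#' Write tract alleles to FASTA
#'
#' One record per haplotype; the header encodes the allele ID and, when
#' available, the truth class (`id class=S`). Sequences are the full
#' haplotype (5' flank + interior + 3' flank).
#'
#' @param alleles Named list of `tract_allele`s.
#' @param path Output file.
#' @export
write_alleles_fasta <- function(alleles, path) {
  seqs <- vapply(alleles, function(a) {
    paste0(a$flank5, allele_interior(a), a$flank3)
  }, "")
  ids <- vapply(alleles, function(a) {
    cls <- a$meta$class
    if (is.null(cls)) a$allele_id else paste0(a$allele_id, " class=", cls)
  }, "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read haplotype sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the full headers).
#' @export
read_haplotypes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write or read a variant catalog as TSV
#'
#' @param catalog A `variant_catalog`.
#' @param path File path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_integer_
  new_variant_catalog(df)
}

#' Write unit decomposition of alleles as TSV
#'
#' Long format: one row per unit (`allele_id`, `unit_index` 0-based,
#' `unit_sequence`, `variant_id`).
#'
#' @param alleles Named list of `tract_allele`s.
#' @param path File path.
#' @export
write_units_tsv <- function(alleles, path) {
  rows <- lapply(alleles, function(a) {
    data.frame(allele_id = a$allele_id,
               unit_index = seq_along(a$units) - 1L,
               unit_sequence = a$units, variant_id = a$unit_ids,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write phased SNP haplotypes as a minimal VCF
#'
#' Sites are written on one pseudo-chromosome with phased `GT` fields built
#' from consecutive haplotype-row pairs of the matrix.
#'
#' @param snps 0/1 haplotype-by-site matrix with an even number of rows
#'   (pairs of rows = individuals, as in a `vntr_cohort`).
#' @param path Output file.
#' @param ids Optional individual IDs (default derived from row names).
#' @export
write_snps_vcf <- function(snps, path, ids = NULL) {
  n_hap <- nrow(snps)
  stopifnot(n_hap %% 2L == 0L)
  n <- n_hap / 2L
  if (is.null(ids)) {
    ids <- unique(sub("_h[12]$", "", rownames(snps)))
    if (length(ids) != n) ids <- sprintf("I%04d", seq_len(n))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=sim>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(ncol(snps))) {
    gt <- paste0(snps[seq(1L, n_hap, 2L), j], "|", snps[seq(2L, n_hap, 2L), j])
    writeLines(paste(c("sim", j * 1000L, colnames(snps)[j], "A", "G", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Parses phased `GT` fields of biallelic sites into a 0/1 haplotype-by-site
#' matrix (two rows per sample, `id_h1`/`id_h2`).
#'
#' @param path VCF file (uncompressed).
#' @return 0/1 matrix, haplotypes x sites.
#' @export
read_snps_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  stopifnot(length(hdr) == 1L)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  site_ids <- character(length(body))
  mat <- matrix(0L, nrow = 2L * length(ids), ncol = length(body),
                dimnames = list(paste0(rep(ids, each = 2L), "_h", 1:2), NULL))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    site_ids[k] <- f[3L]
    gt <- f[-(1:9)]
    parts <- strsplit(gt, "|", fixed = TRUE)
    mat[seq(1L, nrow(mat), 2L), k] <- as.integer(vapply(parts, `[[`, "", 1L))
    mat[seq(2L, nrow(mat), 2L), k] <- as.integer(vapply(parts, `[[`, "", 2L))
  }
  colnames(mat) <- site_ids
  mat
}

#' Write reads as FASTQ
#'
#' @param read_set A `read_set`.
#' @param path Output file.
#' @export
write_reads_fastq <- function(read_set, path) {
  reads <- read_set$reads
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0L) {
    quals <- vapply(nchar(reads), function(n) strrep("I", n), "")
    writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", quals),
               con)
  }
  invisible(path)
}

#' Write an expression matrix and covariates as TSV
#'
#' @param expression_sim An `expression_sim` (see [simulate_expression()]).
#' @param expr_path,covar_path Output files.
#' @export
write_expression_tsv <- function(expression_sim, expr_path, covar_path) {
  utils::write.table(expression_sim$expr, expr_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(expression_sim$covariates, covar_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(expr_path)
}
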