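#' Genotype matrix container
#'
#' Bundles a samples-by-SNPs matrix of additive genotype codes with per-SNP
#' metadata. Codes count copies of the alternate allele: 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternate); `NA` marks a
#' missing call. SNPs are stored sorted by chromosome then position, and
#' positions must be unique within a chromosome.
#'
#' @param calls Integer matrix, samples in rows and SNPs in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param snps Data frame with one row per SNP column: `chrom`, `pos`
#'   (1-based), `ref`, `alt`, and optionally `snp_id` (defaults to
#'   `"chrom:pos"`).
#' @param samples Character vector of sample identifiers; defaults to the
#'   row names of `calls`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (the coded matrix, dimnames set), `snps` (tibble of SNP metadata) and
#'   `samples`.
#' @export
geno_matrix <- function(calls, snps, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- tibble::as_tibble(snps)
  stopifnot(ncol(calls) == nrow(snps))
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  stopifnot(length(samples) == nrow(calls))
  needed <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols) > 0) {
    stop("snps metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"snp_id" %in% names(snps)) {
    snps$snp_id <- paste0(snps$chrom, ":", snps$pos)
  }
  snps <- dplyr::relocate(snps, "snp_id", "chrom", "pos", "ref", "alt")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0) {
    stop("genotype codes must be 0, 1, 2 or NA; found: ",
         paste(unique(bad), collapse = ", "))
  }
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (any(duplicated(snps[c("chrom", "pos")]))) {
    stop("duplicate SNP positions within a chromosome")
  }
  dimnames(calls) <- list(samples, snps$snp_id)
  structure(
    list(calls = calls, snps = snps, samples = as.character(samples)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$calls))
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (%d chromosome(s), %s missing calls)\n",
    nrow(x$calls), ncol(x$calls),
    dplyr::n_distinct(x$snps$chrom), format(n_miss, big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Expression matrix container
#'
#' Bundles a genes-by-samples TPM matrix with gene models and, optionally, a
#' normalized counterpart on the same dimensions.
#'
#' @param tpm Numeric matrix of non-negative TPM values, genes in rows,
#'   samples in columns.
#' @param genes Data frame with one row per gene: `gene_id`, `chrom`,
#'   `start`, `end` (1-based, `start <= end`) and optionally `strand`.
#' @param samples Character vector of sample identifiers; defaults to the
#'   column names of `tpm`.
#' @param normalized Optional matrix of normalized values with the same
#'   dimensions as `tpm`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(tpm, genes, samples = colnames(tpm), normalized = NULL) {
  tpm <- as.matrix(tpm)
  genes <- tibble::as_tibble(genes)
  stopifnot(nrow(tpm) == nrow(genes))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(tpm)))
  stopifnot(length(samples) == ncol(tpm))
  needed <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene models lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  if (any(genes$start > genes$end)) stop("gene models must satisfy start <= end")
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  dimnames(tpm) <- list(genes$gene_id, samples)
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    stopifnot(all(dim(normalized) == dim(tpm)))
    dimnames(normalized) <- dimnames(tpm)
  }
  structure(
    list(tpm = tpm, genes = genes, samples = as.character(samples),
         normalized = normalized),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples%s\n",
    nrow(x$tpm), ncol(x$tpm),
    if (is.null(x$normalized)) "" else " (normalized layer attached)"
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$tpm)

# internal: align two sample vectors, error on mismatch
check_sample_alignment <- function(a, b, what_a = "first", what_b = "second") {
  if (length(a) != length(b) || !all(a == b)) {
    stop("sample identifiers of the ", what_a, " and ", what_b,
         " inputs are not aligned; reorder them to a shared sample order")
  }
  invisible(TRUE)
}
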