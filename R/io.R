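#' Read and write coded genotype tables
#'
#' The TSV layout has one row per SNP: `snp_id`, `chrom`, `pos`, `ref`,
#' `alt`, then one column per sample holding the 0/1/2 code (empty or `NA`
#' for missing).
#'
#' @param geno A [geno_matrix()].
#' @param path File path.
#' @return `write_geno_tsv()` returns `path` invisibly; `read_geno_tsv()`
#'   returns a [geno_matrix()].
#' @export
write_geno_tsv <- function(geno, path) {
  tab <- dplyr::bind_cols(geno$snps,
                          tibble::as_tibble(t(geno$calls)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(chrom = "character"))
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  calls <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  geno_matrix(calls, tab[, meta_cols], samples = rownames(calls))
}

#' Write genotypes as VCF
#'
#' Minimal VCFv4.2 with a GT FORMAT field, suitable for interchange with
#' standard tooling.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(geno, path) {
  gt <- c("0/0", "0/1", "1/1")
  body <- apply(geno$calls, 2, function(g) {
    ifelse(is.na(g), "./.", gt[g + 1L])
  })  # samples x SNPs
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t"),
    paste(geno$snps$chrom, geno$snps$pos, geno$snps$snp_id, geno$snps$ref,
          geno$snps$alt, ".", "PASS", ".", "GT",
          apply(body, 2, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses the GT field of a biallelic-SNP VCF into alternate-allele codes.
#' Requires the vcfR package.
#'
#' @param path VCF path.
#' @return A [geno_matrix()].
#' @export
read_geno_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  code[clean %in% c("0/0")] <- 0L
  code[clean %in% c("0/1", "1/0")] <- 1L
  code[clean %in% c("1/1")] <- 2L
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  snps <- tibble::tibble(snp_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT)
  geno_matrix(t(code), snps, samples = colnames(gt))
}

#' Read and write expression matrices
#'
#' TSV layout: one row per gene with `gene_id`, `chrom`, `start`, `end`,
#' `strand`, then one TPM column per sample.
#'
#' @param expr An [expr_matrix()].
#' @param path File path.
#' @return `write_expr_tsv()` returns `path` invisibly; `read_expr_tsv()`
#'   an [expr_matrix()].
#' @export
write_expr_tsv <- function(expr, path) {
  tab <- dplyr::bind_cols(expr$genes, tibble::as_tibble(expr$tpm))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(chrom = "character"))
  meta_cols <- c("gene_id", "chrom", "start", "end", "strand")
  tpm <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  expr_matrix(tpm, tab[, intersect(meta_cols, names(tab))])
}

#' Read gene models from GFF3, BED or TSV
#'
#' GFF3 and BED go through rtracklayer; gene rows are taken from GFF3
#' (`type == "gene"` when present). A TSV must already carry `gene_id`,
#' `chrom`, `start`, `end` columns.
#'
#' @param path File path; format inferred from the extension.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3", "bed")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading ", ext, " requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", ]
    }
    id <- if (!is.null(df$ID)) df$ID else if (!is.null(df$name)) df$name
      else if (!is.null(df$gene_id)) df$gene_id
      else paste0("gene", seq_len(nrow(df)))
    tibble::tibble(gene_id = as.character(id),
                   chrom = as.character(df$seqnames),
                   start = df$start, end = df$end,
                   strand = as.character(df$strand))
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = c(chrom = "character"))
    tibble::as_tibble(tab[, intersect(c("gene_id", "chrom", "start", "end",
                                        "strand"), names(tab))])
  }
}

#' Read and write allele-specific count tables
#'
#' Uses the ASEReadCounter column convention (`contig`, `position`,
#' `variantID`, `refAllele`, `altAllele`, `refCount`, `altCount`,
#' `totalCount`) with an extra leading `sample` column for long multi-sample
#' tables.
#'
#' @param counts Count tibble as produced by [simulate_ase_counts()].
#' @param path File path.
#' @return `write_ase_tsv()` returns `path` invisibly; `read_ase_tsv()` the
#'   count tibble in package-internal column names.
#' @export
write_ase_tsv <- function(counts, path) {
  tab <- tibble::tibble(
    sample = counts$sample, contig = counts$chrom, position = counts$pos,
    variantID = counts$snp_id, refAllele = counts$ref,
    altAllele = counts$alt, refCount = counts$ref_count,
    altCount = counts$alt_count, totalCount = counts$total_count
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ase_tsv
#' @export
read_ase_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(contig = "character"))
  out <- tibble::tibble(
    snp_id = tab$variantID, chrom = tab$contig, pos = tab$position,
    ref = tab$refAllele, alt = tab$altAllele, ref_count = tab$refCount,
    alt_count = tab$altCount, totalCount = tab$totalCount
  )
  names(out)[names(out) == "totalCount"] <- "total_count"
  if ("sample" %in% names(tab)) out <- dplyr::bind_cols(
    tibble::tibble(sample = tab$sample), out)
  out
}

#' Export a simulated study to plain-text files
#'
#' Writes the genotype VCF, expression / covariate / trait TSVs, the
#' allele-count table and a ground-truth TSV of planted effects into a
#' directory.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geno_vcf(study$geno, file.path(dir, "genotypes.vcf"))
  write_expr_tsv(study$expr, file.path(dir, "expression.tsv"))
  utils::write.table(study$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ase_tsv(study$ase, file.path(dir, "ase_counts.tsv"))
  truth <- dplyr::bind_rows(
    if (!is.null(study$truth$cis_effects))
      dplyr::mutate(study$truth$cis_effects, kind = "cis_effect"),
    if (!is.null(study$truth$trans_effects))
      dplyr::mutate(study$truth$trans_effects, kind = "trans_effect"),
    if (!is.null(study$truth$ase_theta))
      tibble::tibble(snp = study$truth$ase_theta$snp,
                     beta = study$truth$ase_theta$theta, kind = "ase_theta"),
    if (!is.null(study$truth$trait_targets))
      tibble::tibble(gene = study$truth$trait_targets$gene,
                     beta = study$truth$trait_targets$r,
                     snp = study$truth$trait_targets$trait,
                     kind = "trait_target")
  )
  if (!is.null(truth) && nrow(truth) > 0) {
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
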