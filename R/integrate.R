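#' Trait-expression correlation scan
#'
#' Residualizes the log2-transformed expression of every gene and each trait
#' on the same covariates (sex, slaughter batch and boar as fixed effects,
#' age as a covariate), then computes the Pearson correlation between the
#' two residual vectors with its two-sided p-value, and BH-adjusts within
#' each trait separately.
#'
#' @param expr An [expr_matrix()] (TPM layer is used).
#' @param traits Tibble with a `sample` column and numeric trait columns.
#' @param covariates Covariate tibble aligned to the same samples, or
#'   `NULL` for no adjustment (plain centering).
#' @param fdr Significance threshold on `q` (default 0.05).
#' @param log_offset Offset added before the log2 transform so zero TPM is
#'   representable (default 0.25).
#' @param columns Covariate columns used for residualization.
#' @return Tibble with `gene`, `trait`, `r`, `p`, `q`, `significant`.
#'   Traits with zero variance after residualization are skipped with a
#'   warning.
#' @export
trait_gene_correlation <- function(expr, traits, covariates = NULL,
                                   fdr = 0.05, log_offset = 0.25,
                                   columns = intersect(c("sex", "batch",
                                                         "boar", "age"),
                                                       names(covariates))) {
  check_sample_alignment(expr$samples, traits$sample, "expression", "trait")
  if (!is.null(covariates)) {
    check_sample_alignment(expr$samples, covariates$sample,
                           "expression", "covariate")
  }
  resid_fun <- if (is.null(covariates) || length(columns) == 0) {
    function(v) v - mean(v)
  } else {
    function(v) residualize(v, covariates, columns)
  }
  expr_resid <- t(apply(log2(expr$tpm + log_offset), 1, resid_fun))
  trait_names <- setdiff(names(traits), "sample")
  n <- length(expr$samples)
  out <- purrr::map_dfr(trait_names, function(tr) {
    tv <- resid_fun(traits[[tr]])
    if (sd(tv) < 1e-12) {
      warning("trait '", tr, "' has zero variance after residualization; skipped")
      return(NULL)
    }
    r <- unname(as.vector(expr_resid %*% tv) /
                  (sqrt(rowSums(expr_resid^2)) * sqrt(sum(tv^2))))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    tibble::tibble(gene = rownames(expr_resid), trait = tr, r = r,
                   p = 2 * pt(-abs(tstat), n - 2))
  })
  out <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(out, .data$trait),
                                      q = bh_fdr(.data$p)))
  out$significant <- out$q <= fdr
  dplyr::arrange(out, .data$trait, .data$q)
}

#' Set overlaps of cis-eQTL, trans-eQTL, ASE and trait-correlated genes
#'
#' Computes the class-specific and shared gene counts that summarize how the
#' three analyses corroborate each other, plus the two- and three-way
#' intersections used for the candidate table. `total_genes`, when given,
#' adds the share of all annotated genes showing ASE.
#'
#' @param cis_genes,trans_genes,ase_genes,trait_genes Character vectors of
#'   gene identifiers (one namespace).
#' @param total_genes Optional total annotated gene count for percentage
#'   reporting.
#' @return List of class `overlap_report`: `counts` (named integer vector)
#'   and `genes` (list of the intersection gene sets).
#' @export
overlap_analysis <- function(cis_genes, trans_genes = character(0),
                             ase_genes = character(0),
                             trait_genes = character(0),
                             total_genes = NULL) {
  cis <- unique(cis_genes); trans <- unique(trans_genes)
  ase <- unique(ase_genes); trait <- unique(trait_genes)
  cis_ase <- intersect(cis, ase)
  cis_ase_trait <- intersect(cis_ase, trait)
  counts <- c(
    cis = length(cis), trans = length(trans), ase = length(ase),
    trait = length(trait),
    cis_specific = length(setdiff(cis, trans)),
    trans_specific = length(setdiff(trans, cis)),
    cis_trans_shared = length(intersect(cis, trans)),
    cis_ase = length(cis_ase),
    cis_ase_trait = length(cis_ase_trait)
  )
  report <- list(
    counts = counts,
    genes = list(cis_trans_shared = intersect(cis, trans),
                 cis_ase = cis_ase, cis_ase_trait = cis_ase_trait)
  )
  if (!is.null(total_genes)) {
    report$pct_genes_with_ase <- 100 * length(ase) / total_genes
  }
  structure(report, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  print(x$counts)
  if (!is.null(x$pct_genes_with_ase)) {
    cat(sprintf("genes with ASE: %.2f%% of annotated genes\n",
                x$pct_genes_with_ase))
  }
  invisible(x)
}

#' Same-chromosome partition of trans-regulated genes
#'
#' Splits genes carrying significant trans associations into three classes:
#' genes that also carry a significant cis association on the same
#' chromosome as a trans SNP (suggesting the trans signal tags a common
#' cis-regulatory variant), genes whose trans SNPs lie on the gene's own
#' chromosome but that have no such cis signal, and genes whose trans SNPs
#' all lie on other chromosomes.
#'
#' @param assocs Significant association tibble with `gene`, `snp_id`,
#'   `chrom`, `gene_chrom` and `class` columns.
#' @return List with `partition` (tibble `gene`, `category`), `counts`
#'   (named vector) and `fraction_cis_same_chrom` (class-1 genes over all
#'   trans genes).
#' @export
same_chromosome_trans <- function(assocs) {
  trans <- dplyr::filter(assocs, .data$class == "trans")
  cis <- dplyr::filter(assocs, .data$class == "cis")
  genes <- unique(trans$gene)
  category <- vapply(genes, function(g) {
    trans_chroms <- trans$chrom[trans$gene == g]
    cis_chroms <- cis$chrom[cis$gene == g]
    gene_chrom <- trans$gene_chrom[trans$gene == g][1]
    if (length(intersect(trans_chroms, cis_chroms)) > 0) {
      "cis_same_chrom"
    } else if (gene_chrom %in% trans_chroms) {
      "trans_same_chrom"
    } else {
      "trans_other_chrom"
    }
  }, character(1))
  partition <- tibble::tibble(gene = genes, category = unname(category))
  counts <- c(
    cis_same_chrom = sum(category == "cis_same_chrom"),
    trans_same_chrom = sum(category == "trans_same_chrom"),
    trans_other_chrom = sum(category == "trans_other_chrom")
  )
  list(partition = partition, counts = counts,
       fraction_cis_same_chrom = if (length(genes) > 0)
         unname(counts["cis_same_chrom"]) / length(genes) else NA_real_)
}

#' Candidate-gene report from the triple intersection
#'
#' One row per gene significant in all three analyses. The leading cis SNP
#' is the one with the lowest q (ties broken by smaller p, then lower
#' position); the reported ASE SNP is the one with the most observed
#' heterozygotes (ties by higher ASE ratio, then lower position); every
#' trait correlation at `q <= fdr` is listed. Rows are sorted by ascending
#' eQTL q. An empty intersection yields an empty table.
#'
#' @param assocs Association tibble (cis rows with `gene`, `snp_id`, `pos`,
#'   `p`, `q`, `class`), pre-filtered or not — only rows with
#'   `class == "cis"` and `q <= fdr` are used.
#' @param ase_summaries Population ASE tibble from
#'   [aggregate_ase_population()] with a `gene` column.
#' @param correlations Trait correlation tibble from
#'   [trait_gene_correlation()].
#' @param fdr Significance threshold applied to all three inputs
#'   (default 0.05).
#' @return Tibble with `gene`, `eqtl_snp`, `eqtl_q`, `ase_snp`, `n_het`,
#'   `n_ase`, `ratio` (rounded to 2 decimals), `traits`, `cor`, `cor_q`
#'   (the latter three collapsed comma-separated when a gene has several
#'   significant traits).
#' @export
build_candidate_table <- function(assocs, ase_summaries, correlations,
                                  fdr = 0.05) {
  cis <- dplyr::filter(assocs, .data$class == "cis", .data$q <= fdr)
  ase <- dplyr::filter(ase_summaries, !is.na(.data$gene))
  corr <- dplyr::filter(correlations, .data$q <= fdr)
  genes <- Reduce(intersect, list(unique(cis$gene), unique(ase$gene),
                                  unique(corr$gene)))
  if (length(genes) == 0) {
    return(tibble::tibble(
      gene = character(0), eqtl_snp = character(0), eqtl_q = numeric(0),
      ase_snp = character(0), n_het = integer(0), n_ase = integer(0),
      ratio = numeric(0), traits = character(0), cor = character(0),
      cor_q = character(0)
    ))
  }
  lead_eqtl <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(dplyr::filter(cis, .data$gene %in% genes), .data$gene),
      .data$q, .data$p, .data$pos
    ), n = 1
  )
  lead_ase <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(dplyr::filter(ase, .data$gene %in% genes), .data$gene),
      dplyr::desc(.data$n_het), dplyr::desc(.data$ratio), .data$pos
    ), n = 1
  )
  corr_rows <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(corr, .data$gene %in% genes), .data$gene),
    traits = paste(.data$trait, collapse = ","),
    cor = paste(sprintf("%.2f", .data$r), collapse = ","),
    cor_q = paste(sprintf("%.2e", .data$q), collapse = ","),
    .groups = "drop"
  )
  out <- tibble::tibble(gene = genes)
  out <- dplyr::left_join(
    out,
    dplyr::select(dplyr::ungroup(lead_eqtl), "gene", eqtl_snp = "snp_id",
                  eqtl_q = "q"),
    by = "gene"
  )
  out <- dplyr::left_join(
    out,
    dplyr::mutate(
      dplyr::select(dplyr::ungroup(lead_ase), "gene", ase_snp = "snp_id",
                    "n_het", "n_ase"),
      ratio = round(.data$n_ase / .data$n_het, 2)
    ),
    by = "gene"
  )
  out <- dplyr::left_join(out, corr_rows, by = "gene")
  dplyr::arrange(out, .data$eqtl_q)
}
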