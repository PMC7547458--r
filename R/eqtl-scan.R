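#' Genotype principal components for stratification control
#'
#' Sample scores on the top `k` principal components of the column-centered
#' genotype matrix, the standard correction for population stratification in
#' an association scan. Components are ordered by decreasing variance
#' explained and are mutually orthogonal.
#'
#' @param geno A [geno_matrix()] without missing calls.
#' @param k Number of components (default 5).
#' @return Tibble with `sample` and columns `PC1` ... `PCk`.
#' @export
compute_pca_covariates <- function(geno, k = 5) {
  if (anyNA(geno$calls)) stop("missing calls present; impute first")
  if (nrow(geno$calls) < k + 1) stop("need at least k + 1 samples")
  pr <- prcomp(geno$calls, center = TRUE, scale. = FALSE)
  available <- sum(pr$sdev > 1e-10)
  if (k > available) {
    stop("requested ", k, " components but genotype matrix has rank ",
         available)
  }
  scores <- pr$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble::tibble(sample = geno$samples),
                   tibble::as_tibble(scores))
}

#' Classify SNP-gene pairs as cis or trans
#'
#' A pair is cis iff the SNP lies on the gene's chromosome within the
#' strand-agnostic span `[gene_start - window, gene_end + window]`,
#' boundaries inclusive; every other pair is trans. A wholesale mismatch in
#' chromosome naming conventions (e.g. `"chr5"` against `"5"`) is refused
#' rather than silently classifying everything trans.
#'
#' @param snp_chrom,snp_pos Chromosome and 1-based position of each SNP.
#' @param gene_chrom,gene_start,gene_end Gene model coordinates (recycled
#'   against the SNP vectors).
#' @param window Cis window in bp (default 1 Mb).
#' @return Character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                               gene_end, window = 1e6) {
  a <- unique(as.character(snp_chrom))
  b <- unique(as.character(gene_chrom))
  if (length(intersect(a, b)) == 0) {
    strip <- function(x) sub("^chr", "", x, ignore.case = TRUE)
    if (length(intersect(strip(a), strip(b))) > 0) {
      stop("chromosome naming mismatch between SNPs and gene models: ",
           paste(head(a, 3), collapse = ","), " vs ",
           paste(head(b, 3), collapse = ","))
    }
  }
  cis <- as.character(snp_chrom) == as.character(gene_chrom) &
    snp_pos >= gene_start - window & snp_pos <= gene_end + window
  ifelse(cis, "cis", "trans")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with enforced monotonicity (via
#' [stats::p.adjust()]). In the eQTL pipeline this is applied separately to
#' the cis and the trans test sets.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# internal: merge factor levels carried by fewer than min_n samples into the
# modal level, with a warning (degenerate dummy columns break the scan)
collapse_degenerate_levels <- function(covariates, min_n = 2) {
  for (nm in setdiff(names(covariates), "sample")) {
    x <- covariates[[nm]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      tab <- table(x)
      small <- names(tab)[tab < min_n]
      if (length(small) > 0) {
        warning("covariate '", nm, "': level(s) ",
                paste(small, collapse = ", "),
                " carried by fewer than ", min_n,
                " samples; collapsed into the largest level")
        x <- as.character(x)
        x[x %in% small] <- names(tab)[which.max(tab)]
        x <- factor(x)
      }
      covariates[[nm]] <- droplevels(x)
    }
  }
  covariates
}

#' Genome-wide eQTL scan
#'
#' Tests every SNP against every gene with the fixed linear model
#' `Y = beta * SNP + covariates + e`, where `Y` is normalized expression and
#' the SNP enters through its 0/1/2 alternate-allele code, so `beta` is the
#' allele substitution effect. Covariates (genotype principal components,
#' sex, slaughter batch, boar, age) are projected out of both expression and
#' genotypes once; each pair then reduces to a simple regression with
#' `n - p_cov - 1` residual degrees of freedom, numerically identical to
#' refitting the full design per pair. Pairs are classified cis/trans by
#' [classify_cis_trans()] and BH-adjusted within each class separately.
#'
#' @param geno A [geno_matrix()] without missing calls.
#' @param expr An [expr_matrix()] with a `normalized` layer (see
#'   [normalize_expression()]).
#' @param covariates Tibble with a `sample` column plus covariate columns,
#'   or `NULL` for an intercept-only adjustment.
#' @param window Cis window in bp (default 1 Mb).
#' @return A tibble of class `eqtl_scan` with one row per SNP-gene pair:
#'   `snp_id`, `chrom`, `pos`, `gene`, `gene_chrom`, `beta`, `tstat`, `p`,
#'   `class`, `q`. Monomorphic SNPs are skipped with a warning. Attributes
#'   `n_samples`, `df` and `window` record the scan geometry.
#' @export
scan_eqtl <- function(geno, expr, covariates = NULL, window = 1e6) {
  if (is.null(expr$normalized)) {
    stop("expression matrix has no normalized layer; ",
         "run normalize_expression() first")
  }
  if (anyNA(geno$calls)) stop("missing genotype calls; impute first")
  check_sample_alignment(geno$samples, expr$samples, "genotype", "expression")
  n <- length(geno$samples)
  if (!is.null(covariates)) {
    check_sample_alignment(geno$samples, covariates$sample,
                           "genotype", "covariate")
    covariates <- collapse_degenerate_levels(covariates)
    C <- covariate_design(covariates)
  } else {
    C <- matrix(1, n, 1)
  }
  qr_c <- qr(C)
  p_cov <- qr_c$rank
  df <- n - p_cov - 1
  if (df < 1) stop("not enough residual degrees of freedom")

  G <- geno$calls
  mono <- apply(G, 2, function(g) var(g) == 0)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) skipped")
    G <- G[, !mono, drop = FALSE]
  }
  snps <- geno$snps[!mono, , drop = FALSE]
  Y <- t(expr$normalized)

  Gt <- qr.resid(qr_c, G)
  Yt <- qr.resid(qr_c, Y)
  gg <- colSums(Gt^2)
  yy <- colSums(Yt^2)
  GY <- crossprod(Gt, Yt)                    # SNPs x genes
  beta <- GY / gg
  rss <- pmax(sweep(-GY^2 / gg, 2, yy, `+`), 0)
  se <- sqrt(rss / (df * gg))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)

  out <- tibble::tibble(
    snp_id = rep(snps$snp_id, times = ncol(Y)),
    chrom = rep(snps$chrom, times = ncol(Y)),
    pos = rep(snps$pos, times = ncol(Y)),
    gene = rep(colnames(Y), each = nrow(snps)),
    beta = as.vector(beta),
    tstat = as.vector(tstat),
    p = as.vector(pval)
  )
  gi <- match(out$gene, expr$genes$gene_id)
  out$gene_chrom <- expr$genes$chrom[gi]
  out$class <- classify_cis_trans(out$chrom, out$pos, out$gene_chrom,
                                  expr$genes$start[gi], expr$genes$end[gi],
                                  window = window)
  out <- dplyr::group_by(out, .data$class)
  out <- dplyr::mutate(out, q = bh_fdr(.data$p))
  out <- dplyr::ungroup(out)
  attr(out, "n_samples") <- n
  attr(out, "df") <- df
  attr(out, "window") <- window
  class(out) <- c("eqtl_scan", class(out))
  out
}

#' Genomic inflation factor
#'
#' The median association chi-square divided by the null 1-df median
#' (`qchisq(0.5, 1)` = 0.4549). Supply either t statistics with their
#' residual degrees of freedom — they are converted to 1-df chi-squares
#' through their two-sided p-values — or p-values directly. A value near 1
#' indicates that stratification is well controlled.
#'
#' @param tstats Numeric vector of t statistics.
#' @param df Residual degrees of freedom of the t statistics.
#' @param pvalues Alternative input: two-sided p-values.
#' @return The inflation factor lambda (scalar).
#' @export
genomic_inflation <- function(tstats = NULL, df = NULL, pvalues = NULL) {
  if (is.null(pvalues)) {
    if (is.null(tstats) || is.null(df)) {
      stop("supply either t statistics with df, or p-values")
    }
    pvalues <- 2 * pt(-abs(tstats), df)
  }
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0) stop("no tests supplied")
  if (length(pvalues) < 100) {
    warning("fewer than 100 tests; the inflation estimate is unstable")
  }
  chisq <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  unname(median(chisq) / qchisq(0.5, df = 1))
}

#' eQTL pleiotropy and hotspot summary
#'
#' Counts, per significant SNP, how many distinct genes it is associated
#' with, separately for cis and trans. Counts are binned 1, 2, 3, 4, 5 and
#' >=6; the fraction of SNPs associated with two or more genes is reported
#' per class, and SNPs above `hotspot_min` genes form the hotspot table.
#'
#' @param assocs An association tibble with `snp_id`, `chrom`, `pos`,
#'   `gene`, `class` and `q` columns (e.g. from [scan_eqtl()]).
#' @param q_max Significance threshold on `q` (default 0.05).
#' @param hotspot_min A SNP is a hotspot when its gene count exceeds this
#'   (default 3).
#' @return List with `bins` (tibble `class`, `bin`, `n_snps`),
#'   `fraction_multi` (tibble `class`, `n_snps`, `n_multi`, `fraction`) and
#'   `hotspots` (tibble `snp_id`, `chrom`, `pos`, `class`, `n_genes`).
#' @export
pleiotropy_summary <- function(assocs, q_max = 0.05, hotspot_min = 3) {
  sig <- dplyr::filter(assocs, .data$q <= q_max)
  per_snp <- dplyr::summarise(
    dplyr::group_by(sig, .data$class, .data$snp_id, .data$chrom, .data$pos),
    n_genes = dplyr::n_distinct(.data$gene), .groups = "drop"
  )
  bin_levels <- c("1", "2", "3", "4", "5", ">=6")
  per_snp$bin <- factor(ifelse(per_snp$n_genes >= 6, ">=6",
                               as.character(per_snp$n_genes)),
                        levels = bin_levels)
  bins <- dplyr::count(per_snp, .data$class, .data$bin, name = "n_snps",
                       .drop = FALSE)
  fraction_multi <- dplyr::summarise(
    dplyr::group_by(per_snp, .data$class),
    n_snps = dplyr::n(), n_multi = sum(.data$n_genes >= 2),
    fraction = .data$n_multi / .data$n_snps, .groups = "drop"
  )
  hotspots <- dplyr::arrange(
    dplyr::filter(per_snp, .data$n_genes > hotspot_min),
    dplyr::desc(.data$n_genes)
  )[, c("snp_id", "chrom", "pos", "class", "n_genes")]
  list(bins = bins, fraction_multi = fraction_multi, hotspots = hotspots)
}
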