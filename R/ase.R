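#' Filter allele count records to informative sites
#'
#' A sample-by-SNP record is informative when it has at least `min_total`
#' total reads, at least `min_allele` allele-specific reads, and each
#' allele's reads exceed `min_fraction` of the total. The read-count minimum
#' is applied per allele by default (`allele_mode = "each"`: both reference
#' and alternate need `min_allele` reads, consistent with the per-allele
#' percentage rule); `allele_mode = "total"` is the laxer reading requiring
#' `min_allele` reads summed over both alleles.
#'
#' @param counts Tibble with `ref_count`, `alt_count` and `total_count`
#'   columns (e.g. ASEReadCounter-style output or [simulate_ase_counts()]).
#' @param min_total Minimum total reads (default 10).
#' @param min_allele Minimum allele-specific reads (default 3).
#' @param min_fraction Each allele's reads must exceed this fraction of the
#'   total (default 0.01).
#' @param allele_mode `"each"` (default) or `"total"`, see above.
#' @return The filtered tibble.
#' @export
filter_informative <- function(counts, min_total = 10, min_allele = 3,
                               min_fraction = 0.01,
                               allele_mode = c("each", "total")) {
  allele_mode <- match.arg(allele_mode)
  stopifnot(all(counts$ref_count >= 0), all(counts$alt_count >= 0),
            all(counts$ref_count + counts$alt_count <= counts$total_count))
  allele_ok <- if (allele_mode == "each") {
    counts$ref_count >= min_allele & counts$alt_count >= min_allele
  } else {
    counts$ref_count + counts$alt_count >= min_allele
  }
  keep <- counts$total_count >= min_total & allele_ok &
    counts$ref_count / counts$total_count > min_fraction &
    counts$alt_count / counts$total_count > min_fraction
  counts[keep, , drop = FALSE]
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial p-value of the reference-allele count against a
#' null reference fraction `theta0`, computed as `min(1, 2 *` smaller-tail
#' probability`)`. At the default `theta0 = 0.5` the null is symmetric, the
#' statistic is symmetric in its arguments, and the value coincides with
#' R's exact binomial test. Vectorized.
#'
#' @param ref_count,alt_count Non-negative allele read counts (the binomial
#'   denominator is their sum; reads carrying other alleles are excluded).
#' @param theta0 Null reference-allele probability (default 0.5).
#' @return Vector of p-values in `(0, 1]`.
#' @export
ase_binom_test <- function(ref_count, alt_count, theta0 = 0.5) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    stop("read counts must be non-negative")
  }
  n <- ref_count + alt_count
  if (any(n < 1)) stop("need at least one allele-specific read")
  lower <- pbinom(ref_count, n, theta0)
  upper <- pbinom(ref_count - 1, n, theta0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Call allele-specific expression within one sample
#'
#' Applies the exact binomial test to each informative site and
#' Benjamini-Hochberg adjustment across the sample's sites only (FDR is
#' controlled per sample). A site is significant at `q <= fdr`.
#'
#' @param counts Informative count tibble for a single sample (pre-filter
#'   with [filter_informative()]); must contain `ref_count` and `alt_count`.
#' @param fdr FDR level (default 0.05).
#' @param theta0 Null reference fraction (default 0.5).
#' @return The tibble with `allelic_ratio`, `p`, `q` and `significant`
#'   columns appended. Empty input returns an empty tibble.
#' @export
call_ase_sample <- function(counts, fdr = 0.05, theta0 = 0.5) {
  if (nrow(counts) == 0) {
    return(dplyr::mutate(counts, allelic_ratio = numeric(0), p = numeric(0),
                         q = numeric(0), significant = logical(0)))
  }
  counts$allelic_ratio <- counts$ref_count /
    (counts$ref_count + counts$alt_count)
  counts$p <- ase_binom_test(counts$ref_count, counts$alt_count, theta0)
  counts$q <- bh_fdr(counts$p)
  counts$significant <- counts$q <= fdr
  counts
}

#' Call allele-specific expression across samples
#'
#' Filters to informative sites and runs [call_ase_sample()] per sample.
#'
#' @param counts Long count tibble with a `sample` column.
#' @param fdr,theta0 Passed to [call_ase_sample()].
#' @param ... Passed to [filter_informative()].
#' @return Tibble of per-sample calls.
#' @export
call_ase <- function(counts, fdr = 0.05, theta0 = 0.5, ...) {
  informative <- filter_informative(counts, ...)
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(informative, .data$sample),
    ~ call_ase_sample(.x, fdr = fdr, theta0 = theta0)
  ))
}

#' Population-level aggregation of ASE calls
#'
#' Per SNP, counts the heterozygous samples with informative calls
#' (`n_het`) and those significant for allelic imbalance (`n_ase`), keeps
#' SNPs with `n_het >= min_het` and `n_ase >= min_ase_het`, and reports the
#' ratio `n_ase / n_het`. When gene models are supplied each SNP is
#' annotated with the gene body (or bodies) overlapping its position;
#' SNPs inside no gene stay unannotated (`NA`).
#'
#' @param calls Call tibble from [call_ase()]; rows should be heterozygous
#'   sample-by-SNP cells (a `genotype` column, if present, restricts to
#'   code 1 automatically).
#' @param gene_models Optional tibble with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param min_het Minimum heterozygote count (default 30).
#' @param min_ase_het Minimum ASE-significant heterozygote count
#'   (default 10).
#' @return Tibble with `snp_id`, `chrom`, `pos`, `n_het`, `n_ase`, `ratio`
#'   and (when annotated) `gene`.
#' @export
aggregate_ase_population <- function(calls, gene_models = NULL,
                                     min_het = 30, min_ase_het = 10) {
  if ("genotype" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$genotype == 1L)
  }
  summ <- dplyr::summarise(
    dplyr::group_by(calls, .data$snp_id, .data$chrom, .data$pos),
    n_het = dplyr::n(), n_ase = sum(.data$significant),
    .groups = "drop"
  )
  summ <- dplyr::filter(summ, .data$n_het >= min_het,
                        .data$n_ase >= min_ase_het)
  summ$ratio <- summ$n_ase / summ$n_het
  if (!is.null(gene_models)) {
    gm <- tibble::as_tibble(gene_models)
    hits <- dplyr::select(
      dplyr::filter(
        dplyr::inner_join(summ[c("snp_id", "chrom", "pos")], gm,
                          by = "chrom", relationship = "many-to-many"),
        .data$pos >= .data$start, .data$pos <= .data$end
      ),
      "snp_id", gene = "gene_id"
    )
    summ <- dplyr::left_join(summ, hits, by = "snp_id",
                             relationship = "many-to-many")
  }
  dplyr::arrange(summ, .data$chrom, .data$pos)
}

#' Reference allelic-ratio distribution
#'
#' Diagnostic for residual reference mapping bias: the per-site reference
#' allelic ratio `ref / (ref + alt)` over informative counts, summarized by
#' mean and median, a histogram over `[0, 1]` in bins of 0.02, and the
#' fractions falling in the bands above 0.51, below 0.49 and between. A
#' symmetric distribution centred on 0.5 indicates little residual bias.
#'
#' @param counts Informative count tibble with `ref_count`, `alt_count`.
#' @return List of class `ase_ratio_summary`: `stats` (tibble with `n`,
#'   `mean`, `median`, `frac_above_0.51`, `frac_below_0.49`,
#'   `frac_between`), `histogram` (tibble `bin_lower`, `bin_upper`, `n`)
#'   and `ratios` (the per-site ratios).
#' @export
allelic_ratio_distribution <- function(counts) {
  ratio <- counts$ref_count / (counts$ref_count + counts$alt_count)
  breaks <- seq(0, 1, by = 0.02)
  bin_counts <- tabulate(findInterval(ratio, breaks, rightmost.closed = TRUE),
                         nbins = length(breaks) - 1)
  structure(
    list(
      stats = tibble::tibble(
        n = length(ratio), mean = mean(ratio), median = median(ratio),
        frac_above_0.51 = mean(ratio > 0.51),
        frac_below_0.49 = mean(ratio < 0.49),
        frac_between = mean(ratio >= 0.49 & ratio <= 0.51)
      ),
      histogram = tibble::tibble(
        bin_lower = head(breaks, -1), bin_upper = breaks[-1], n = bin_counts
      ),
      ratios = ratio
    ),
    class = "ase_ratio_summary"
  )
}

#' @export
print.ase_ratio_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<ase_ratio_summary> %d sites; mean ratio %.3f, median %.3f; >0.51: %.1f%%, <0.49: %.1f%%\n",
    s$n, s$mean, s$median, 100 * s$frac_above_0.51, 100 * s$frac_below_0.49
  ))
  invisible(x)
}
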