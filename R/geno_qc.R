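#' Minor-allele-frequency and missingness filters
#'
#' Mirrors the usual PLINK-style quality control: samples whose missing-call
#' rate exceeds `mind_missing_max` are dropped first, then SNPs with minor
#' allele frequency below `maf_min` or missing rate above `geno_missing_max`.
#' MAF is computed from non-missing calls only. Boundaries are kept: a SNP
#' exactly at the MAF threshold or a sample exactly at the missing-rate
#' threshold survives.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param geno_missing_max Maximum per-SNP missing rate (default 0.1).
#' @param mind_missing_max Maximum per-sample missing rate (default 0.15).
#' @return The filtered [geno_matrix()], with a `qc_log` attribute (tibble
#'   of removal counts per filter).
#' @export
filter_variants <- function(geno, maf_min = 0.01, geno_missing_max = 0.1,
                            mind_missing_max = 0.15) {
  stopifnot(maf_min >= 0, maf_min <= 1, geno_missing_max >= 0,
            geno_missing_max <= 1, mind_missing_max >= 0,
            mind_missing_max <= 1)
  calls <- geno$calls
  sample_miss <- rowMeans(is.na(calls))
  keep_samples <- sample_miss <= mind_missing_max
  calls <- calls[keep_samples, , drop = FALSE]

  snp_miss <- colMeans(is.na(calls))
  p_alt <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0  # SNPs with no calls left
  keep_snps <- maf >= maf_min & snp_miss <= geno_missing_max
  if (!any(keep_snps) || !any(keep_samples)) {
    stop("no samples or SNPs survive variant filtering")
  }
  out <- geno_matrix(calls[, keep_snps, drop = FALSE],
                     geno$snps[keep_snps, ],
                     geno$samples[keep_samples])
  attr(out, "qc_log") <- tibble::tibble(
    filter = c("mind_missing", "maf", "geno_missing"),
    removed = c(sum(!keep_samples),
                sum(maf < maf_min),
                sum(maf >= maf_min & snp_miss > geno_missing_max))
  )
  out
}

#' Genotype-class median filter
#'
#' Guards against extreme genotype distributions in populations where a
#' Hardy-Weinberg test is inappropriate (such as an F1 cross of divergent
#' breeds, where heterozygotes dominate at breed-fixed loci). Per SNP the
#' samples in each of the three genotype classes are counted and the SNP is
#' kept iff the median of the three class counts is at least
#' `ceiling(fraction * n_samples)` — with 189 samples and the default
#' fraction 0.10 that is the >= 19 rule.
#'
#' @param geno A [geno_matrix()] with no missing calls (impute first).
#' @param fraction Fraction of the sample count the median class must reach
#'   (default 0.10).
#' @return The filtered [geno_matrix()].
#' @export
genotype_median_filter <- function(geno, fraction = 0.10) {
  if (anyNA(geno$calls)) {
    stop("missing genotype calls present; impute first ",
         "(see impute_missing_mode())")
  }
  n <- nrow(geno$calls)
  threshold <- ceiling(fraction * n)
  med <- apply(geno$calls, 2, function(g) {
    median(c(sum(g == 0L), sum(g == 1L), sum(g == 2L)))
  })
  keep <- med >= threshold
  if (!any(keep)) stop("no SNPs survive the genotype-class median filter")
  geno_matrix(geno$calls[, keep, drop = FALSE], geno$snps[keep, ],
              geno$samples)
}

#' Modal imputation of missing genotype calls
#'
#' Replaces each missing call by the SNP's most frequent genotype among the
#' observed calls; ties are broken toward the lower code.
#'
#' @param geno A [geno_matrix()].
#' @return A [geno_matrix()] without missing calls.
#' @export
impute_missing_mode <- function(geno) {
  calls <- geno$calls
  all_missing <- colSums(!is.na(calls)) == 0
  if (any(all_missing)) {
    stop("SNP(s) entirely missing, cannot impute: ",
         paste(head(geno$snps$snp_id[all_missing], 5), collapse = ", "))
  }
  for (j in which(colSums(is.na(calls)) > 0)) {
    counts <- tabulate(calls[, j] + 1L, nbins = 3L)
    mode_code <- which.max(counts) - 1L  # which.max takes the first maximum
    calls[is.na(calls[, j]), j] <- mode_code
  }
  geno_matrix(calls, geno$snps, geno$samples)
}

# internal: match SNPs of two matrices by chrom+pos, detecting ref/alt
# swaps. Returns tibble(idx_truth, idx_test, swapped).
match_common_snps <- function(truth, test) {
  key_t <- paste(truth$snps$chrom, truth$snps$pos)
  key_s <- paste(test$snps$chrom, test$snps$pos)
  m <- match(key_t, key_s)
  idx_truth <- which(!is.na(m))
  idx_test <- m[idx_truth]
  same <- truth$snps$ref[idx_truth] == test$snps$ref[idx_test] &
    truth$snps$alt[idx_truth] == test$snps$alt[idx_test]
  swapped <- truth$snps$ref[idx_truth] == test$snps$alt[idx_test] &
    truth$snps$alt[idx_truth] == test$snps$ref[idx_test]
  keep <- same | swapped
  tibble::tibble(idx_truth = idx_truth[keep], idx_test = idx_test[keep],
                 swapped = swapped[keep])
}

# internal: aligned call matrices on common samples and SNPs, with test
# codes flipped 0<->2 where ref/alt are swapped
align_for_comparison <- function(truth, test) {
  common_samples <- intersect(truth$samples, test$samples)
  if (length(common_samples) == 0) stop("no common samples")
  snp_map <- match_common_snps(truth, test)
  if (nrow(snp_map) == 0) {
    stop("no common SNPs between the two genotype matrices ",
         "(matching requires chrom, pos and allele agreement)")
  }
  a <- truth$calls[common_samples, snp_map$idx_truth, drop = FALSE]
  b <- test$calls[common_samples, snp_map$idx_test, drop = FALSE]
  if (any(snp_map$swapped)) {
    b[, snp_map$swapped] <- 2L - b[, snp_map$swapped, drop = FALSE]
  }
  colnames(a) <- colnames(b) <- truth$snps$snp_id[snp_map$idx_truth]
  list(truth = a, test = b, samples = common_samples,
       snp_id = truth$snps$snp_id[snp_map$idx_truth],
       n_swapped = sum(snp_map$swapped))
}

#' Genotyping concordance between two platforms
#'
#' Compares two genotype matrices (for instance array calls against calls
#' derived from RNA-seq) over their common SNPs, matched by chromosome,
#' position and alleles. When reference and alternate alleles are swapped
#' between the platforms the codes of the second matrix are flipped 0<->2
#' before comparison. Per sample, consistency is the fraction of compared
#' calls that agree; cells missing in either matrix are excluded from the
#' denominator.
#'
#' @param truth,test [geno_matrix()] objects sharing samples and SNPs.
#' @return Tibble with `sample`, `n_compared`, `n_match`, `consistency`.
#' @export
genotype_concordance <- function(truth, test) {
  al <- align_for_comparison(truth, test)
  ok <- !is.na(al$truth) & !is.na(al$test)
  match_mat <- al$truth == al$test & ok
  tibble::tibble(
    sample = al$samples,
    n_compared = unname(rowSums(ok)),
    n_match = unname(rowSums(match_mat)),
    consistency = unname(rowSums(match_mat) / rowSums(ok))
  )
}

#' Heterozygote genotyping precision
#'
#' Among cells the test matrix calls heterozygous, the fraction the truth
#' matrix also calls heterozygous — true-positive heterozygotes over true
#' plus false positive heterozygotes — reported per common SNP and pooled
#' over all of them. SNPs at which the test matrix makes no heterozygous
#' call have undefined precision and are returned as `NA`.
#'
#' @param truth,test [geno_matrix()] objects sharing samples and SNPs.
#' @return List with `per_snp` (tibble of `snp_id`, `n_test_het`,
#'   `n_true_het`, `precision`) and `overall` (pooled precision).
#' @export
heterozygote_precision <- function(truth, test) {
  al <- align_for_comparison(truth, test)
  test_het <- !is.na(al$test) & al$test == 1L & !is.na(al$truth)
  true_het <- test_het & al$truth == 1L
  n_test <- colSums(test_het)
  n_true <- colSums(true_het)
  per_snp <- tibble::tibble(
    snp_id = al$snp_id, n_test_het = unname(n_test),
    n_true_het = unname(n_true),
    precision = unname(ifelse(n_test > 0, n_true / n_test, NA_real_))
  )
  overall <- if (sum(n_test) > 0) sum(n_true) / sum(n_test) else NA_real_
  list(per_snp = per_snp, overall = overall)
}
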