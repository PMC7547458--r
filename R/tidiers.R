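#' Tidy a heritability fit
#'
#' @param x A `herit_fit` from [reml_heritability()].
#' @param ... Unused.
#' @return One-row tibble with `h2`, `sigma_g2`, `sigma_e2`, `loglik`.
#' @exportS3Method generics::tidy
tidy.herit_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 loglik = x$loglik)
}

#' @rdname tidy.herit_fit
#' @return `glance()` adds the sample size `n`.
#' @exportS3Method generics::glance
glance.herit_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, loglik = x$loglik, n = x$n)
}

#' Tidy an eQTL scan
#'
#' The scan result already is a tibble; `tidy()` strips the class so it
#' prints plainly, `glance()` summarizes it: numbers of tests, significant
#' associations, SNPs and genes per class at `q <= 0.05`, and the genomic
#' inflation factor over all tests.
#'
#' @param x An `eqtl_scan` from [scan_eqtl()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eqtl_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.eqtl_scan
#' @param q_max Significance threshold used by `glance()` (default 0.05).
#' @exportS3Method generics::glance
glance.eqtl_scan <- function(x, q_max = 0.05, ...) {
  sig <- dplyr::filter(tibble::as_tibble(x), .data$q <= q_max)
  per_class <- dplyr::summarise(
    dplyr::group_by(sig, .data$class),
    n_assoc = dplyr::n(), n_snps = dplyr::n_distinct(.data$snp_id),
    n_genes = dplyr::n_distinct(.data$gene), .groups = "drop"
  )
  tibble::tibble(
    n_tests = nrow(x),
    n_cis_assoc = pull_or_zero(per_class, "cis", "n_assoc"),
    n_cis_snps = pull_or_zero(per_class, "cis", "n_snps"),
    n_cis_genes = pull_or_zero(per_class, "cis", "n_genes"),
    n_trans_assoc = pull_or_zero(per_class, "trans", "n_assoc"),
    n_trans_snps = pull_or_zero(per_class, "trans", "n_snps"),
    n_trans_genes = pull_or_zero(per_class, "trans", "n_genes"),
    lambda = genomic_inflation(pvalues = x$p)
  )
}

pull_or_zero <- function(tab, cls, col) {
  v <- tab[[col]][tab$class == cls]
  if (length(v) == 0) 0L else v
}
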