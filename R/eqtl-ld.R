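#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by EM over the 3x3
#' genotype table (the double heterozygote being the only ambiguous cell),
#' then reports `D' = |D| / D_max` and `r^2 = D^2 / (pA qA pB qB)` where
#' `D = p_AB - pA pB` and A/B denote the alternate alleles of the two SNPs.
#'
#' @param geno A [geno_matrix()].
#' @param snp_a,snp_b SNP identifiers (`snp_id` values).
#' @param tol EM convergence threshold on the largest frequency change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000); non-convergence is
#'   an error reporting the iteration count.
#' @return One-row tibble: `snp_a`, `snp_b`, `dprime`, `r2`, and the
#'   estimated haplotype frequencies `p_AB`, `p_Ab`, `p_aB`, `p_ab`
#'   (summing to 1).
#' @export
ld_pairwise <- function(geno, snp_a, snp_b, tol = 1e-8, max_iter = 1000) {
  g1 <- geno$calls[, match_snp(geno, snp_a)]
  g2 <- geno$calls[, match_snp(geno, snp_b)]
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (var(g1) == 0 || var(g2) == 0) {
    stop("both SNPs must be polymorphic")
  }
  n <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  N <- 2 * length(g1)
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  # start at linkage equilibrium; non-double-het cells pull the estimate
  # toward the data immediately
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    x <- if (denom > 0) unname(p["AB"] * p["ab"] / denom) else 0.5
    cnt <- c(
      AB = 2 * n[3, 3] + n[3, 2] + n[2, 3] + x * n[2, 2],
      Ab = 2 * n[3, 1] + n[3, 2] + n[2, 1] + (1 - x) * n[2, 2],
      aB = 2 * n[1, 3] + n[1, 2] + n[2, 3] + (1 - x) * n[2, 2],
      ab = 2 * n[1, 1] + n[1, 2] + n[2, 1] + x * n[2, 2]
    )
    p_new <- cnt / N
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("haplotype-frequency EM did not converge within ", max_iter,
         " iterations")
  }
  pA <- p["AB"] + p["Ab"]
  pB <- p["AB"] + p["aB"]
  D <- unname(p["AB"] - pA * pB)
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (d_max > 0) abs(D) / d_max else 0
  r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  tibble::tibble(
    snp_a = snp_a, snp_b = snp_b,
    dprime = unname(dprime), r2 = r2,
    p_AB = unname(p["AB"]), p_Ab = unname(p["Ab"]),
    p_aB = unname(p["aB"]), p_ab = unname(p["ab"])
  )
}

match_snp <- function(geno, snp) {
  idx <- match(snp, geno$snps$snp_id)
  if (is.na(idx)) stop("unknown SNP: ", snp)
  idx
}
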