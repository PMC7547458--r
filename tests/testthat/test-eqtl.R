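test_that("genotype PCs separate divergent subpopulations and are orthogonal", {
  set.seed(6)
  n_per <- 40; m <- 300
  calls <- rbind(
    matrix(rbinom(n_per * m, 2, 0.15), nrow = n_per),
    matrix(rbinom(n_per * m, 2, 0.65), nrow = n_per)
  )
  g <- toy_geno(calls)
  pcs <- compute_pca_covariates(g, k = 5)
  expect_equal(setdiff(names(pcs), "sample"), paste0("PC", 1:5))
  pc1 <- pcs$PC1
  # the two groups do not overlap on PC1
  expect_true(max(pc1[1:n_per]) < min(pc1[(n_per + 1):(2 * n_per)]) ||
                min(pc1[1:n_per]) > max(pc1[(n_per + 1):(2 * n_per)]))
  scores <- as.matrix(pcs[, -1])
  cross <- crossprod(scores)
  expect_true(all(abs(cross[upper.tri(cross)]) < 1e-8))
})

test_that("cis/trans classification uses the inclusive 1 Mb window", {
  # gene chr5:86,000,000-86,050,000
  expect_equal(classify_cis_trans("5", 85200000, "5", 86000000, 86050000),
               "cis")
  expect_equal(classify_cis_trans("5", 87100000, "5", 86000000, 86050000),
               "trans")
  expect_equal(classify_cis_trans("6", 86000000, "5", 86000000, 86050000),
               "trans")
  # inclusive boundaries
  expect_equal(classify_cis_trans("5", 85000000, "5", 86000000, 86050000),
               "cis")
  expect_equal(classify_cis_trans("5", 84999999, "5", 86000000, 86050000),
               "trans")
  expect_error(classify_cis_trans("chr5", 1, "5", 1, 2), "naming mismatch")
})

test_that("the projected scan equals per-pair full-design OLS", {
  set.seed(7)
  n <- 60
  g <- toy_geno(matrix(rbinom(n * 12, 2, 0.4), nrow = n),
                chrom = rep(c("1", "2"), each = 6),
                pos = rep(c(1e6 * 1:6), 2))
  norm <- matrix(rnorm(12 * n), nrow = 12)
  e <- toy_expr(matrix(rexp(12 * n), nrow = 12),
                chrom = rep(c("1", "2"), 6),
                start = rep(2e6 * 1:6, 2), end = rep(2e6 * 1:6 + 1e4, 2),
                normalized = norm)
  cov <- tibble::tibble(
    sample = paste0("S", 1:n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = sample(c("b1", "b2", "b3"), n, replace = TRUE),
    age = rnorm(n, 210, 6)
  )
  scan <- scan_eqtl(g, e, cov)
  oracle <- oracle_scan(g, e, cov)
  merged <- dplyr::inner_join(scan, oracle, by = c("snp_id", "gene"),
                              suffix = c("", "_o"))
  expect_equal(nrow(merged), 144)
  expect_equal(merged$beta, merged$beta_o, tolerance = 1e-8)
  expect_equal(merged$tstat, merged$tstat_o, tolerance = 1e-8)
  expect_equal(merged$p, merged$p_o, tolerance = 1e-8)
})

test_that("an exact genotype-expression identity gives beta 1 and vanishing p", {
  set.seed(8)
  n <- 50
  calls <- matrix(rbinom(n * 3, 2, 0.5), nrow = n)
  g <- toy_geno(calls)
  norm <- rbind(as.numeric(calls[, 1]), rnorm(n))
  e <- toy_expr(matrix(1, 2, n), normalized = norm)
  scan <- scan_eqtl(g, e)
  hit <- dplyr::filter(scan, snp_id == g$snps$snp_id[1], gene == "g1")
  expect_equal(hit$beta, 1, tolerance = 1e-12)
  expect_lt(hit$p, 1e-100)
})

test_that("null scans produce uniform p-values and monomorphic SNPs are skipped", {
  set.seed(9)
  n <- 100
  calls <- matrix(rbinom(n * 200, 2, 0.3), nrow = n)
  calls[, 1] <- 1L  # monomorphic
  g <- toy_geno(calls, chrom = "1", pos = 1000L * (1:200))
  norm <- matrix(rnorm(10 * n), nrow = 10)
  e <- toy_expr(matrix(1, 10, n), chrom = "2", normalized = norm)
  expect_warning(scan <- scan_eqtl(g, e), "monomorphic")
  expect_false(any(scan$snp_id == "1:1000"))
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.8))
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))  # all equal: q = p
  expect_equal(bh_fdr(0.07), 0.07)                # single p: q = p
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(10)
  p <- runif(500)
  expect_equal(bh_fdr(p), oracle_bh(p))
  # monotone in p and never below p
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("genomic inflation is calibrated on null tests and scales with chi-square", {
  set.seed(11)
  p <- runif(20000)
  expect_lt(abs(genomic_inflation(pvalues = p) - 1), 0.05)
  # doubling every chi-square doubles lambda
  x <- qchisq(p, 1, lower.tail = FALSE)
  lam1 <- genomic_inflation(pvalues = pchisq(x, 1, lower.tail = FALSE))
  lam2 <- genomic_inflation(pvalues = pchisq(2 * x, 1, lower.tail = FALSE))
  expect_equal(lam2 / lam1, 2, tolerance = 1e-6)
  expect_warning(genomic_inflation(pvalues = 0.5), "fewer than 100")
  expect_error(genomic_inflation(pvalues = numeric(0)), "no tests")
})

test_that("the GRM has unit mean diagonal in an unrelated population", {
  set.seed(12)
  n <- 150; m <- 5000
  freqs <- runif(m, 0.05, 0.95)
  calls <- matrix(rbinom(n * m, 2, rep(freqs, each = n)), nrow = n)
  g <- toy_geno(calls)
  grm <- compute_grm(g)
  expect_identical(grm, t(grm))
  expect_lt(abs(mean(diag(grm)) - 1), 0.05)
})

test_that("duplicated samples share their diagonal relationship", {
  set.seed(13)
  calls <- matrix(rbinom(10 * 50, 2, 0.5), nrow = 10)
  calls[2, ] <- calls[1, ]
  grm <- compute_grm(toy_geno(calls))
  expect_equal(grm[1, 2], grm[1, 1])
  expect_equal(grm[1, 2], grm[2, 2])
  mono <- toy_geno(cbind(rep(0L, 10), rep(2L, 10)))
  expect_error(suppressWarnings(compute_grm(mono)), "at least 2 polymorphic")
})

test_that("REML heritability matches a dense grid-search oracle on a toy", {
  set.seed(14)
  n <- 20
  calls <- matrix(rbinom(n * 80, 2, 0.5), nrow = n)
  g <- toy_geno(calls)
  K <- compute_grm(g)
  X <- cbind(1, rnorm(n))
  cov <- tibble::tibble(sample = g$samples, age = X[, 2])
  for (i in 1:3) {
    y <- as.numeric(chol(K + 0.05 * diag(n)) %*% rnorm(n)) + rnorm(n)
    fit <- reml_heritability(y, K, cov, columns = "age")
    h2_grid <- oracle_reml_grid(y, K, X)
    expect_lt(abs(fit$h2 - h2_grid), 0.01)
    # reported loglik agrees with the dense-solve oracle at the optimum
    expect_equal(fit$loglik, oracle_reml_loglik(min(fit$h2, 1 - 1e-9), y, K, X),
                 tolerance = 1e-4)
  }
})

test_that("REML returns near-zero heritability for a purely environmental trait", {
  set.seed(15)
  n <- 300
  calls <- matrix(rbinom(n * 400, 2, 0.5), nrow = n)
  K <- compute_grm(toy_geno(calls))
  fit <- reml_heritability(rnorm(n), K)
  expect_lt(fit$h2, 0.1)
  expect_gte(fit$sigma_g2, 0)
  expect_gte(fit$sigma_e2, 0)
  tt <- tidy(fit)
  expect_equal(tt$h2, fit$h2)
  expect_equal(glance(fit)$n, n)
})

test_that("non-PSD relationship matrices are refused", {
  bad <- diag(5); bad[1, 1] <- -1
  expect_error(reml_heritability(rnorm(5), bad), "positive semi-definite")
})

test_that("LD statistics match the closed form on phased-equivalent data", {
  # haplotype counts AB=40, ab=40, Ab=10, aB=10 paired into unambiguous
  # homozygous-pair individuals: D' = 0.6, r2 = 0.36
  calls1 <- c(rep(2L, 20), rep(0L, 20), rep(2L, 5), rep(0L, 5))
  calls2 <- c(rep(2L, 20), rep(0L, 20), rep(0L, 5), rep(2L, 5))
  g <- toy_geno(cbind(calls1, calls2))
  ld <- ld_pairwise(g, g$snps$snp_id[1], g$snps$snp_id[2])
  expect_equal(ld$dprime, 0.6, tolerance = 1e-6)
  expect_equal(ld$r2, 0.36, tolerance = 1e-6)
  expect_equal(ld$p_AB + ld$p_Ab + ld$p_aB + ld$p_ab, 1, tolerance = 1e-9)
  expect_equal(c(ld$p_AB, ld$p_Ab, ld$p_aB, ld$p_ab),
               c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-6)
})

test_that("perfectly correlated SNPs reach D' = 1 and r2 = 1", {
  set.seed(16)
  x <- rbinom(200, 2, 0.4)
  g <- toy_geno(cbind(x, x))
  ld <- ld_pairwise(g, g$snps$snp_id[1], g$snps$snp_id[2])
  expect_equal(ld$dprime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
})

test_that("independent SNPs show negligible LD and r2 tracks genotype correlation", {
  set.seed(17)
  n <- 2000
  g <- toy_geno(cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.6)))
  ld <- ld_pairwise(g, g$snps$snp_id[1], g$snps$snp_id[2])
  expect_lt(ld$r2, 0.01)

  # HWE pair with planted LD: EM r2 agrees with squared genotype correlation
  hap_freq <- c(AB = 0.4, Ab = 0.1, aB = 0.1, ab = 0.4)
  hap <- sample(1:4, 2 * n, replace = TRUE, prob = hap_freq)
  a <- matrix(as.integer(hap %in% c(1, 2)), ncol = 2)  # allele A indicator
  b <- matrix(as.integer(hap %in% c(1, 3)), ncol = 2)
  g2 <- toy_geno(cbind(rowSums(a), rowSums(b)))
  ld2 <- ld_pairwise(g2, g2$snps$snp_id[1], g2$snps$snp_id[2])
  expect_lt(abs(ld2$r2 - cor(rowSums(a), rowSums(b))^2), 0.02)
})

test_that("pleiotropy summary bins SNPs by associated gene count", {
  mk <- function(snp, genes, class) {
    tibble::tibble(snp_id = snp, chrom = "1", pos = 1L, gene = genes,
                   class = class, q = 0.01)
  }
  assocs <- dplyr::bind_rows(
    mk("1:1", paste0("g", 1:9), "cis"),   # nine genes: the >=6 bin
    mk("1:2", paste0("g", 1:2), "cis"),
    mk("1:3", "g1", "cis"),
    mk("1:4", "g9", "trans")
  )
  pl <- pleiotropy_summary(assocs)
  bins <- dplyr::filter(pl$bins, class == "cis")
  expect_equal(bins$n_snps[bins$bin == ">=6"], 1)
  expect_equal(bins$n_snps[bins$bin == "2"], 1)
  fm <- dplyr::filter(pl$fraction_multi, class == "cis")
  expect_equal(fm$fraction, 2 / 3)
  expect_equal(pl$hotspots$snp_id, "1:1")  # > 3 genes

  single <- pleiotropy_summary(mk(paste0("1:", 1:5), paste0("g", 1:5), "cis"))
  expect_equal(single$fraction_multi$fraction, 0)
  expect_equal(nrow(single$hotspots), 0)
})

test_that("planted cis effects surface as significant cis associations", {
  cfg <- sim_config(n_snps = 80, n_genes = 10, n_chrom = 3, seed = 99)
  st <- simulate_study(cfg, n_cis = 3, cis_beta = 1.5)
  g <- filter_variants(impute_missing_mode(st$geno), maf_min = 0.01)
  pcs <- compute_pca_covariates(g, 5)
  cov <- dplyr::left_join(st$covariates, pcs, by = "sample")
  # scan on the generative scale so the estimated allele-substitution
  # effect is directly comparable to the planted one (the rank-based
  # transform would compress it toward unit variance)
  scan <- scan_eqtl(g, st$expr, cov)
  truth <- dplyr::select(dplyr::rename(st$truth$cis_effects, snp_id = snp),
                         "snp_id", "gene")
  planted <- dplyr::inner_join(tibble::as_tibble(scan), truth,
                               by = c("snp_id", "gene"))
  expect_equal(nrow(planted), 3)
  expect_true(all(planted$class == "cis"))
  expect_true(all(planted$q <= 0.05))
  expect_true(all(abs(planted$beta - 1.5) < 0.5))
  gl <- glance(scan)
  expect_gte(gl$n_cis_assoc, 3)
})
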