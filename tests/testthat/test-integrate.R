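test_that("trait-gene correlation equals the Pearson oracle on residuals", {
  set.seed(22)
  n <- 60
  cov <- tibble::tibble(
    sample = paste0("S", 1:n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = sample(paste0("b", 1:3), n, replace = TRUE),
    boar = sample(paste0("sire", 1:4), n, replace = TRUE),
    age = rnorm(n, 210, 6)
  )
  tpm <- matrix(rexp(8 * n, 0.2), nrow = 8)
  e <- toy_expr(tpm, samples = cov$sample)
  traits <- tibble::tibble(sample = cov$sample, pH_24h = rnorm(n, 5.6),
                           mean_B = rnorm(n, 4))
  res <- trait_gene_correlation(e, traits, cov)
  for (i in c(1, 5)) {
    for (tr in c("pH_24h", "mean_B")) {
      x <- residualize(log2(tpm[i, ] + 0.25), cov)
      y <- residualize(traits[[tr]], cov)
      ct <- cor.test(x, y)
      row <- dplyr::filter(res, gene == paste0("g", i), trait == tr)
      expect_equal(row$r, unname(ct$estimate), tolerance = 1e-10)
      expect_equal(row$p, ct$p.value, tolerance = 1e-8)
    }
  }
  # BH is applied within each trait separately
  for (tr in c("pH_24h", "mean_B")) {
    sub <- dplyr::filter(res, trait == tr)
    expect_equal(sub$q, bh_fdr(sub$p))
  }
})

test_that("a gene tracking a trait exactly reaches r = 1", {
  n <- 30
  trait_val <- rnorm(n, 6)
  e <- toy_expr(rbind(2^trait_val, rexp(n)), samples = paste0("S", 1:n))
  traits <- tibble::tibble(sample = paste0("S", 1:n), pH_45min = trait_val)
  res <- trait_gene_correlation(e, traits, covariates = NULL, log_offset = 0)
  expect_equal(dplyr::filter(res, gene == "g1")$r, 1, tolerance = 1e-6)
})

test_that("constant traits are skipped with a warning", {
  n <- 20
  e <- toy_expr(matrix(rexp(2 * n), nrow = 2), samples = paste0("S", 1:n))
  traits <- tibble::tibble(sample = paste0("S", 1:n), flat = rep(5, n),
                           ok = rnorm(n))
  expect_warning(res <- trait_gene_correlation(e, traits, NULL), "flat")
  expect_setequal(unique(res$trait), "ok")
})

test_that("overlap analysis reproduces set arithmetic", {
  mk <- function(prefix, n) paste0(prefix, seq_len(n))
  shared <- mk("s", 422)
  cis <- c(shared, mk("c", 2098 - 422))
  trans <- c(shared, mk("t", 863 - 422))
  rep <- overlap_analysis(cis, trans)
  expect_equal(unname(rep$counts["cis_specific"]), 1676)
  expect_equal(unname(rep$counts["trans_specific"]), 441)
  expect_equal(unname(rep$counts["cis_trans_shared"]), 422)
  # inclusion-exclusion holds exactly
  expect_equal(rep$counts[["cis"]],
               rep$counts[["cis_specific"]] + rep$counts[["cis_trans_shared"]])

  disjoint <- overlap_analysis(c("a", "b"), c("c"), c("d"), c("e"))
  expect_equal(unname(disjoint$counts["cis_trans_shared"]), 0)
  expect_equal(unname(disjoint$counts["cis_ase_trait"]), 0)

  same <- overlap_analysis(c("a", "b"), c("a", "b"))
  expect_equal(unname(same$counts["cis_specific"]), 0)
  expect_equal(unname(same$counts["cis_trans_shared"]), 2)
})

test_that("trans-genes are partitioned by same-chromosome cis support", {
  assoc <- function(gene, snp_chrom, class, gene_chrom = "14") {
    tibble::tibble(gene = gene, snp_id = paste0(snp_chrom, ":1"),
                   chrom = snp_chrom, gene_chrom = gene_chrom, class = class)
  }
  assocs <- dplyr::bind_rows(
    assoc("gA", "14", "trans"), assoc("gA", "14", "cis"),   # class 1
    assoc("gB", "14", "trans"),                             # class 2
    assoc("gC", "6", "trans", gene_chrom = "9"),            # class 3
    assoc("gD", "2", "trans", gene_chrom = "9"),
    assoc("gD", "9", "cis", gene_chrom = "9")               # cis elsewhere
  )
  part <- same_chromosome_trans(assocs)
  expect_equal(part$counts[["cis_same_chrom"]], 1)
  expect_equal(part$counts[["trans_same_chrom"]], 1)
  expect_equal(part$counts[["trans_other_chrom"]], 2)
  expect_equal(part$fraction_cis_same_chrom, 0.25)
  cat_d <- part$partition$category[part$partition$gene == "gD"]
  expect_equal(cat_d, "trans_other_chrom")
})

test_that("the candidate table joins the triple intersection with tie rules", {
  cis <- tibble::tibble(
    gene = c("gene1", "gene1", "gene2", "gene3"),
    snp_id = c("1:100", "1:50", "2:10", "3:10"),
    pos = c(100L, 50L, 10L, 10L),
    p = c(1e-8, 1e-8, 1e-4, 1e-5), q = c(1e-6, 1e-6, 1e-3, 1e-4),
    class = "cis"
  )
  ase <- tibble::tibble(
    snp_id = c("1:60", "1:70", "2:11"), chrom = c("1", "1", "2"),
    pos = c(60L, 70L, 11L),
    n_het = c(109L, 109L, 74L), n_ase = c(102L, 90L, 73L),
    ratio = c(102 / 109, 90 / 109, 73 / 74),
    gene = c("gene1", "gene1", "gene2")
  )
  corr <- tibble::tibble(
    gene = c("gene1", "gene2", "gene3"), trait = c("pH_45min", "mean_B", "mean_L"),
    r = c(0.35, -0.28, 0.4), p = c(1e-4, 1e-3, 0.2), q = c(6.9e-4, 2.7e-2, 0.4)
  )
  tab <- build_candidate_table(cis, ase, corr)
  # gene3's correlation is not significant: excluded
  expect_setequal(tab$gene, c("gene1", "gene2"))
  # leading eQTL SNP tie on q and p broken by lower position
  g1 <- dplyr::filter(tab, gene == "gene1")
  expect_equal(g1$eqtl_snp, "1:50")
  # ASE SNP tie on n_het broken by higher ratio
  expect_equal(g1$ase_snp, "1:60")
  expect_equal(g1$ratio, 0.94)
  g2 <- dplyr::filter(tab, gene == "gene2")
  expect_equal(g2$ratio, 0.99)
  # sorted by ascending eQTL q
  expect_equal(tab$gene, c("gene1", "gene2"))

  empty <- build_candidate_table(cis[0, ], ase, corr)
  expect_equal(nrow(empty), 0)
})

test_that("null trait correlations stay calibrated", {
  set.seed(23)
  n <- 189
  tpm <- matrix(rexp(300 * n, 0.2), nrow = 300)
  e <- toy_expr(tpm, samples = paste0("S", 1:n))
  traits <- tibble::tibble(sample = paste0("S", 1:n), pH_24h = rnorm(n))
  res <- trait_gene_correlation(e, traits, NULL)
  expect_lt(mean(res$significant), 0.05 + 0.02)
})

test_that("genes planted with cis, ASE and trait signals reach the candidate table", {
  recovered <- 0; spurious <- 0; n_planted <- 0; n_unplanted <- 0
  for (i in 1:20) {
    cfg <- sim_config(n_offspring = 189, n_snps = 60, n_genes = 8,
                      n_chrom = 3, seed = 8000 + i)
    st <- simulate_study(cfg, n_cis = 3, cis_beta = 1, n_ase = 3,
                         ase_theta_value = 0.8, n_trait = 3, trait_r = 0.5)
    g <- filter_variants(impute_missing_mode(st$geno))
    pcs <- compute_pca_covariates(g, 5)
    cov <- dplyr::left_join(st$covariates, pcs, by = "sample")
    scan <- suppressWarnings(
      scan_eqtl(g, normalize_expression(st$expr), cov))
    summ <- aggregate_ase_population(call_ase(st$ase),
                                     gene_models = st$expr$genes)
    corr <- trait_gene_correlation(st$expr, st$traits, st$covariates)
    tab <- build_candidate_table(scan, summ, corr)
    planted <- st$truth$cis_effects$gene
    recovered <- recovered + sum(planted %in% tab$gene)
    n_planted <- n_planted + length(planted)
    other <- setdiff(st$expr$genes$gene_id, planted)
    spurious <- spurious + sum(other %in% tab$gene)
    n_unplanted <- n_unplanted + length(other)
  }
  expect_gte(recovered / n_planted, 0.80)
  expect_lte(spurious / n_unplanted, 0.05)
})
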