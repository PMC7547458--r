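#' Configuration for the synthetic F1-cross study generator
#'
#' Describes a simulated F1 population produced by crossing sires from one
#' founder breed with dams from a second, divergent breed, together with the
#' planted signals the downstream analysis is expected to recover: additive
#' cis/trans effects on normalized expression, allelic imbalance at
#' heterozygous sites, and gene-trait correlations.
#'
#' @param n_offspring Number of F1 offspring (default 189).
#' @param n_sires,n_dams Founder counts (defaults 8 and 158).
#' @param n_snps,n_genes Marker and gene counts.
#' @param n_chrom Number of chromosomes markers and genes are spread over.
#' @param chrom_length Chromosome length in bp.
#' @param founder_freq_a,founder_freq_b Alternate-allele frequency of each
#'   SNP in the sire and dam breeds: a scalar, a vector of length `n_snps`,
#'   or `NULL` to draw each frequency uniformly on (0, 1). Values must lie
#'   in `[0, 1]`; fixation (0 or 1) is allowed and is what makes an F1 cross
#'   heterozygote-rich.
#' @param cis_effects,trans_effects Data frames with columns `gene`, `snp`,
#'   `beta` giving planted allele-substitution effects on the normalized
#'   expression scale, or `NULL` for none.
#' @param ase_theta Data frame with columns `snp`, `theta` giving the
#'   reference-allele expression fraction at heterozygotes (theta strictly
#'   inside (0, 1)), or `NULL` for a balanced 0.5 everywhere.
#' @param ase_snps SNP identifiers to emit allele read counts for; `NULL`
#'   means every SNP.
#' @param depth_mean,depth_dispersion Mean and dispersion (negative-binomial
#'   `size`) of per-site read depth; default mean 30.
#' @param trait_targets Data frame with columns `trait`, `gene`, `r` giving
#'   target Pearson correlations (|r| < 1) between a trait and a gene's
#'   expression, or `NULL`.
#' @param covariate_effects Named list of effect-magnitude standard
#'   deviations for `sex` (2 levels), `batch` (4 slaughter batches), `boar`
#'   (the sire) and `age` (slope per day around the 210-day mean).
#' @param noise_sd Residual standard deviation of expression.
#' @param ld_block_size Optional number of consecutive SNPs per founder
#'   haplotype block; within a block alleles are drawn comonotonically so
#'   neighbouring SNPs are in strong linkage disequilibrium. `NULL` (the
#'   default) draws every SNP independently.
#' @param seed Integer seed; identical configurations reproduce identical
#'   outputs bit for bit.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_offspring = 189, n_sires = 8, n_dams = 158,
                       n_snps = 500, n_genes = 50,
                       n_chrom = 5, chrom_length = 1e8,
                       founder_freq_a = NULL, founder_freq_b = NULL,
                       cis_effects = NULL, trans_effects = NULL,
                       ase_theta = NULL, ase_snps = NULL,
                       depth_mean = 30, depth_dispersion = 5,
                       trait_targets = NULL,
                       covariate_effects = list(sex = 0.3, batch = 0.3,
                                                boar = 0.3, age = 0.01),
                       noise_sd = 1, ld_block_size = NULL, seed = 1) {
  cfg <- structure(
    list(n_offspring = n_offspring, n_sires = n_sires, n_dams = n_dams,
         n_snps = n_snps, n_genes = n_genes, n_chrom = n_chrom,
         chrom_length = chrom_length,
         founder_freq_a = founder_freq_a, founder_freq_b = founder_freq_b,
         cis_effects = cis_effects, trans_effects = trans_effects,
         ase_theta = ase_theta, ase_snps = ase_snps,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         trait_targets = trait_targets,
         covariate_effects = covariate_effects,
         noise_sd = noise_sd, ld_block_size = ld_block_size,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(n_offspring = cfg$n_offspring, n_sires = cfg$n_sires,
              n_dams = cfg$n_dams, n_snps = cfg$n_snps,
              n_genes = cfg$n_genes, n_chrom = cfg$n_chrom)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    stop("all counts in sim_config must be positive integers")
  }
  check_freq <- function(f, label) {
    if (is.null(f)) return(invisible(NULL))
    if (!length(f) %in% c(1L, cfg$n_snps)) {
      stop(label, " must be a scalar or of length n_snps")
    }
    if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
      stop(label, " must be finite and within [0, 1]")
    }
  }
  check_freq(cfg$founder_freq_a, "founder_freq_a")
  check_freq(cfg$founder_freq_b, "founder_freq_b")
  if (!is.null(cfg$ase_theta)) {
    th <- cfg$ase_theta$theta
    if (any(!is.finite(th)) || any(th <= 0) || any(th >= 1)) {
      stop("ase_theta values must lie strictly inside (0, 1)")
    }
  }
  if (!is.null(cfg$trait_targets) && any(abs(cfg$trait_targets$r) >= 1)) {
    stop("trait target correlations must satisfy |r| < 1")
  }
  if (cfg$depth_mean <= 0 || cfg$depth_dispersion <= 0) {
    stop("read-depth model parameters must be positive")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

# Deterministic marker map: positions drawn without replacement per
# chromosome so they are unique, then sorted.
sim_snp_map <- function(cfg) {
  withr::with_seed(cfg$seed + 11L, {
    chrom <- sort(sample.int(cfg$n_chrom, cfg$n_snps, replace = TRUE))
    pos <- unlist(lapply(split(seq_along(chrom), chrom), function(idx) {
      sort(sample.int(cfg$chrom_length, length(idx)))
    }), use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, cfg$n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    tibble::tibble(chrom = as.character(chrom), pos = pos, ref = ref,
                   alt = unname(alt))
  })
}

#' Gene models for a simulated study
#'
#' Places `n_genes` gene bodies on the simulated chromosome map. Each gene
#' is anchored on one marker so that its body contains at least one SNP —
#' the situation of variants called from RNA-seq reads, which by
#' construction fall inside transcripts and can therefore report
#' allele-specific expression for the surrounding gene. Deterministic under
#' the configuration seed so that genotype and expression generation agree
#' on the same models.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
sim_gene_models <- function(cfg) {
  snps <- sim_snp_map(cfg)
  withr::with_seed(cfg$seed + 17L, {
    anchor <- sample.int(nrow(snps), cfg$n_genes,
                         replace = cfg$n_genes > nrow(snps))
    len <- sample(5000:50000, cfg$n_genes, replace = TRUE)
    offset <- floor(len * runif(cfg$n_genes, 0.1, 0.9))
    start <- pmax(1L, snps$pos[anchor] - offset)
    tibble::tibble(
      gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
      chrom = snps$chrom[anchor], start = start, end = start + len,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    )
  })
}

#' Simulate F1 genotypes from two founder breeds
#'
#' Founder haplotypes are drawn per breed from the configured allele
#' frequencies; each offspring receives one allele sampled from its sire's
#' two haplotypes and one from its dam's, per SNP. When both breeds are
#' fixed for opposite alleles every offspring is heterozygous, the situation
#' that makes an F1 cross powerful for allele-specific expression.
#'
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()] with a `pedigree` attribute (tibble of
#'   `sample`, `sire`, `dam`).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  snps <- sim_snp_map(cfg)
  n <- cfg$n_offspring
  withr::with_seed(cfg$seed + 101L, {
    freq_a <- resolve_freq(cfg$founder_freq_a, cfg$n_snps)
    freq_b <- resolve_freq(cfg$founder_freq_b, cfg$n_snps)
    hap_a <- draw_haplotypes(2L * cfg$n_sires, freq_a, cfg$ld_block_size)
    hap_b <- draw_haplotypes(2L * cfg$n_dams, freq_b, cfg$ld_block_size)
    sire <- sample.int(cfg$n_sires, n, replace = TRUE)
    dam <- sample.int(cfg$n_dams, n, replace = TRUE)
    pick <- function(hap, parent) {
      # one transmitted allele per SNP: choose between the parent's two
      # haplotypes independently per site (no within-parent linkage), or
      # per block in block-LD mode so that founder LD survives transmission
      if (is.null(cfg$ld_block_size)) {
        choice <- matrix(sample.int(2L, n * cfg$n_snps, replace = TRUE),
                         nrow = n)
      } else {
        block <- (seq_len(cfg$n_snps) - 1L) %/% cfg$ld_block_size + 1L
        per_block <- matrix(sample.int(2L, n * max(block), replace = TRUE),
                            nrow = n)
        choice <- per_block[, block, drop = FALSE]
      }
      row1 <- hap[2L * parent - 1L, , drop = FALSE]
      row2 <- hap[2L * parent, , drop = FALSE]
      ifelse(choice == 1L, row1, row2)
    }
    calls <- pick(hap_a, sire) + pick(hap_b, dam)
    rownames(calls) <- sprintf("S%03d", seq_len(n))
    g <- geno_matrix(calls, snps)
    attr(g, "pedigree") <- tibble::tibble(
      sample = g$samples,
      sire = sprintf("sire%02d", sire),
      dam = sprintf("dam%03d", dam)
    )
    attr(g, "founder_freq") <- tibble::tibble(
      snp_id = paste0(snps$chrom, ":", snps$pos),
      freq_a = freq_a, freq_b = freq_b
    )
    g
  })
}

resolve_freq <- function(f, n_snps) {
  if (is.null(f)) return(runif(n_snps))
  if (length(f) == 1L) rep(f, n_snps) else f
}

draw_haplotypes <- function(n_hap, freq, block_size) {
  n_snps <- length(freq)
  if (is.null(block_size)) {
    matrix(rbinom(n_hap * n_snps, 1L, rep(freq, each = n_hap)),
           nrow = n_hap)
  } else {
    # comonotone draws within a block: one uniform per haplotype per block
    block <- (seq_len(n_snps) - 1L) %/% block_size + 1L
    u <- matrix(runif(n_hap * max(block)), nrow = n_hap)
    out <- matrix(0L, n_hap, n_snps)
    for (j in seq_len(n_snps)) out[, j] <- as.integer(u[, block[j]] < freq[j])
    out
  }
}

#' Simulate normalized expression with planted genetic effects
#'
#' Builds expression as the sum of planted SNP effects (additive in the 0/1/2
#' code), covariate effects (sex, slaughter batch, boar, age) and Gaussian
#' noise — i.e. the generative model the association scan assumes. Covariate
#' assignments are drawn here and returned alongside: sex over 2 levels and
#' batch over 4 levels uniformly, boar taken from the pedigree, age normal
#' with mean 210 and standard deviation 6 days.
#'
#' @param geno A [geno_matrix()] from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return List with `expr` (an [expr_matrix()]; the `normalized` layer holds
#'   the generative scale and `tpm` an exponentiated counterpart) and
#'   `covariates` (tibble of `sample`, `sex`, `batch`, `boar`, `age`).
#' @export
simulate_expression <- function(geno, cfg) {
  validate_sim_config(cfg)
  genes <- sim_gene_models(cfg)
  effects <- dplyr::bind_rows(cfg$cis_effects, cfg$trans_effects)
  if (nrow2(effects) > 0) {
    unknown_snp <- setdiff(effects$snp, geno$snps$snp_id)
    unknown_gene <- setdiff(effects$gene, genes$gene_id)
    if (length(unknown_snp) > 0 || length(unknown_gene) > 0) {
      stop("planted effects reference unknown identifiers: ",
           paste(c(unknown_snp, unknown_gene), collapse = ", "))
    }
  }
  n <- length(geno$samples)
  withr::with_seed(cfg$seed + 202L, {
    ped <- attr(geno, "pedigree")
    covariates <- tibble::tibble(
      sample = geno$samples,
      sex = factor(sample(c("F", "M"), n, replace = TRUE)),
      batch = factor(sample(paste0("batch", 1:4), n, replace = TRUE)),
      boar = factor(if (is.null(ped)) {
        sample(sprintf("sire%02d", seq_len(cfg$n_sires)), n, replace = TRUE)
      } else ped$sire),
      age = rnorm(n, 210, 6)
    )
    ce <- cfg$covariate_effects
    Y <- matrix(0, nrow = n, ncol = cfg$n_genes,
                dimnames = list(geno$samples, genes$gene_id))
    for (j in seq_len(cfg$n_genes)) {
      gene <- genes$gene_id[j]
      y <- numeric(n)
      if (nrow2(effects) > 0) {
        for (k in which(effects$gene == gene)) {
          y <- y + effects$beta[k] * geno$calls[, effects$snp[k]]
        }
      }
      y <- y + rnorm(2)[as.integer(covariates$sex)] * ce$sex
      y <- y + rnorm(nlevels(covariates$batch))[as.integer(covariates$batch)] * ce$batch
      y <- y + rnorm(nlevels(covariates$boar))[as.integer(covariates$boar)] * ce$boar
      y <- y + rnorm(1) * ce$age * (covariates$age - 210)
      if (cfg$noise_sd > 0) y <- y + rnorm(n, 0, cfg$noise_sd)
      Y[, j] <- y
    }
    norm <- t(Y)
    expr <- expr_matrix(tpm = 2^(norm + 5), genes = genes,
                        samples = geno$samples, normalized = norm)
    list(expr = expr, covariates = covariates)
  })
}

nrow2 <- function(x) if (is.null(x)) 0L else nrow(x)

#' Simulate allele-specific read counts
#'
#' Per sample and SNP, read depth is negative-binomial; at heterozygous
#' cells the reference-allele count is binomial with the planted
#' reference-expression fraction theta (0.5 where unplanted), and homozygous
#' cells yield reads for the carried allele only.
#'
#' @param geno A [geno_matrix()].
#' @param cfg The [sim_config()]; `ase_snps` restricts which SNPs emit
#'   counts, `ase_theta` plants imbalance.
#' @return Tibble with one row per emitted sample-by-SNP cell: `sample`,
#'   `snp_id`, `chrom`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`,
#'   `total_count`, `genotype`.
#' @export
simulate_ase_counts <- function(geno, cfg) {
  validate_sim_config(cfg)
  snp_ids <- cfg$ase_snps %||% geno$snps$snp_id
  snp_ids <- intersect(snp_ids, geno$snps$snp_id)
  theta <- setNames(rep(0.5, length(snp_ids)), snp_ids)
  if (!is.null(cfg$ase_theta)) {
    planted <- cfg$ase_theta
    keep <- planted$snp %in% snp_ids
    theta[planted$snp[keep]] <- planted$theta[keep]
  }
  meta <- geno$snps[match(snp_ids, geno$snps$snp_id), ]
  withr::with_seed(cfg$seed + 303L, {
    cells <- tidyr::expand_grid(sample = geno$samples, snp_id = snp_ids)
    gt <- geno$calls[cbind(match(cells$sample, geno$samples),
                           match(cells$snp_id, geno$snps$snp_id))]
    cells <- cells[!is.na(gt), ]
    gt <- gt[!is.na(gt)]
    depth <- rnbinom(nrow(cells), mu = cfg$depth_mean,
                     size = cfg$depth_dispersion)
    th <- theta[cells$snp_id]
    ref_count <- integer(nrow(cells))
    het <- gt == 1L
    ref_count[het] <- rbinom(sum(het), depth[het], th[het])
    ref_count[gt == 0L] <- depth[gt == 0L]  # homozygous ref: all reads ref
    # homozygous alt: ref_count stays 0
    m <- match(cells$snp_id, meta$snp_id)
    tibble::tibble(
      sample = cells$sample, snp_id = cells$snp_id,
      chrom = meta$chrom[m], pos = meta$pos[m],
      ref = meta$ref[m], alt = meta$alt[m],
      ref_count = ref_count, alt_count = depth - ref_count,
      total_count = depth, genotype = gt
    )
  })
}

#' Simulate meat-quality traits with planted gene correlations
#'
#' Emits the eight traits measured on the longissimus muscle: meat colour
#' parameters (`mean_L`, `mean_A`, `mean_B`, `mean_C`, `mean_H`), pH at 45
#' minutes and 24 hours post-slaughter, and drip loss. A targeted trait is a
#' mixture `r * z_gene + sqrt(1 - r^2) * noise` of the standardized planted
#' gene's expression, so its Pearson correlation with that gene equals `r`
#' in expectation; untargeted traits are pure noise.
#'
#' @param expr An [expr_matrix()] with a normalized layer.
#' @param cfg The [sim_config()]; `trait_targets` plants the correlations.
#' @return Tibble with `sample` and the eight trait columns.
#' @export
simulate_traits <- function(expr, cfg) {
  validate_sim_config(cfg)
  trait_names <- c("mean_L", "mean_A", "mean_B", "mean_C", "mean_H",
                   "pH_45min", "pH_24h", "drip_loss")
  offsets <- c(mean_L = 48, mean_A = 6, mean_B = 4, mean_C = 8, mean_H = 35,
               pH_45min = 6.4, pH_24h = 5.6, drip_loss = 2.5)
  targets <- cfg$trait_targets
  if (!is.null(targets)) {
    bad <- setdiff(targets$gene, expr$genes$gene_id)
    if (length(bad) > 0) {
      stop("trait targets reference unknown genes: ", paste(bad, collapse = ", "))
    }
    bad_trait <- setdiff(targets$trait, trait_names)
    if (length(bad_trait) > 0) {
      stop("unknown trait name(s): ", paste(bad_trait, collapse = ", "))
    }
  }
  n <- length(expr$samples)
  withr::with_seed(cfg$seed + 404L, {
    out <- tibble::tibble(sample = expr$samples)
    for (tr in trait_names) {
      y <- rnorm(n)
      if (!is.null(targets) && tr %in% targets$trait) {
        row <- targets[match(tr, targets$trait), ]
        z <- as.numeric(scale(expr$normalized[row$gene, ]))
        y <- row$r * z + sqrt(1 - row$r^2) * rnorm(n)
      }
      out[[tr]] <- offsets[[tr]] + y
    }
    out
  })
}

#' Add genotyping errors to a genotype matrix
#'
#' Replaces each non-missing call, independently with probability
#' `error_rate`, by one of the two other codes chosen uniformly. Used to
#' emulate an error-prone second genotyping route (e.g. variant calls from
#' RNA-seq) when exercising concordance metrics: expected per-sample
#' consistency against the original matrix is `1 - error_rate`.
#'
#' @param geno A [geno_matrix()].
#' @param error_rate Per-call error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [geno_matrix()] with perturbed calls.
#' @export
perturb_genotypes <- function(geno, error_rate, seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  withr::with_seed(as.integer(seed), {
    calls <- geno$calls
    idx <- which(!is.na(calls) & matrix(runif(length(calls)) < error_rate,
                                        nrow = nrow(calls)))
    if (length(idx) > 0) {
      old <- calls[idx]
      shift <- sample.int(2L, length(idx), replace = TRUE)
      calls[idx] <- (old + shift) %% 3L
    }
    geno_matrix(calls, geno$snps, geno$samples)
  })
}

#' Run the full synthetic study
#'
#' Generates genotypes, expression, covariates, allele-specific counts and
#' traits from one configuration. When the configuration carries no explicit
#' effect maps, `n_cis`, `n_ase` and `n_trait` plant them automatically:
#' each planted gene is paired with the nearest SNP inside its cis window
#' (for trans effects, a SNP on another chromosome), planted allelic
#' imbalance reuses the cis SNPs, and trait targets reuse the cis genes.
#'
#' @param cfg A [sim_config()].
#' @param n_cis,n_trans,n_ase,n_trait Numbers of effects to auto-plant when
#'   the corresponding map in `cfg` is `NULL`.
#' @param cis_beta,trans_beta,ase_theta_value,trait_r Planted magnitudes for
#'   auto-planting.
#' @param window Cis window in bp used when pairing genes with SNPs.
#' @return List with `geno`, `expr`, `covariates`, `ase`, `traits`,
#'   `pedigree`, `truth` (the planted maps) and `cfg` (the completed
#'   configuration).
#' @export
simulate_study <- function(cfg, n_cis = 0, n_trans = 0, n_ase = 0,
                           n_trait = 0, cis_beta = 1, trans_beta = 1,
                           ase_theta_value = 0.8, trait_r = 0.5,
                           window = 1e6) {
  geno <- simulate_genotypes(cfg)
  genes <- sim_gene_models(cfg)
  if (is.null(cfg$cis_effects) && n_cis > 0) {
    cfg$cis_effects <- plant_cis(geno, genes, n_cis, cis_beta, window,
                                 cfg$seed + 21L)
  }
  if (is.null(cfg$trans_effects) && n_trans > 0) {
    cfg$trans_effects <- plant_trans(geno, genes, n_trans, trans_beta,
                                     cfg$cis_effects, cfg$seed + 22L)
  }
  if (is.null(cfg$ase_theta) && n_ase > 0) {
    snps <- cfg$cis_effects$snp %||% character(0)
    if (length(snps) < n_ase) {
      extra <- setdiff(geno$snps$snp_id, snps)
      snps <- c(snps, extra[seq_len(n_ase - length(snps))])
    }
    cfg$ase_theta <- tibble::tibble(snp = snps[seq_len(n_ase)],
                                    theta = ase_theta_value)
  }
  sim_expr <- simulate_expression(geno, cfg)
  if (is.null(cfg$trait_targets) && n_trait > 0) {
    trait_names <- c("pH_45min", "pH_24h", "mean_B", "mean_L", "mean_H",
                     "mean_A", "mean_C", "drip_loss")
    genes_t <- cfg$cis_effects$gene %||% genes$gene_id
    n_trait <- min(n_trait, length(trait_names), length(genes_t))
    cfg$trait_targets <- tibble::tibble(
      trait = trait_names[seq_len(n_trait)],
      gene = genes_t[seq_len(n_trait)], r = trait_r
    )
  }
  ase <- simulate_ase_counts(geno, cfg)
  traits <- simulate_traits(sim_expr$expr, cfg)
  list(
    geno = geno, expr = sim_expr$expr, covariates = sim_expr$covariates,
    ase = ase, traits = traits, pedigree = attr(geno, "pedigree"),
    truth = list(cis_effects = cfg$cis_effects,
                 trans_effects = cfg$trans_effects,
                 ase_theta = cfg$ase_theta,
                 trait_targets = cfg$trait_targets),
    cfg = cfg
  )
}

plant_cis <- function(geno, genes, n_cis, beta, window, seed) {
  snps <- geno$snps
  picks <- purrr::map_dfr(seq_len(nrow(genes)), function(j) {
    g <- genes[j, ]
    cand <- snps[snps$chrom == g$chrom & snps$pos >= g$start - window &
                   snps$pos <= g$end + window, ]
    if (nrow(cand) == 0) return(NULL)
    sub <- geno$calls[, cand$snp_id, drop = FALSE]
    maf <- pmin(colMeans(sub) / 2, 1 - colMeans(sub) / 2)
    # informative for association: common AND variable (an all-heterozygous
    # breed-fixed locus has MAF 0.5 but zero variance)
    cand <- cand[maf[cand$snp_id] >= 0.1 &
                   apply(sub, 2, var)[cand$snp_id] > 0, ]
    if (nrow(cand) == 0) return(NULL)
    # prefer an informative SNP inside the gene body (it can then report
    # allele-specific expression for the same gene); fall back to the
    # nearest one in the window
    in_body <- cand$pos >= g$start & cand$pos <= g$end
    mid <- (g$start + g$end) / 2
    cand <- cand[order(!in_body, abs(cand$pos - mid)), ]
    tibble::tibble(gene = g$gene_id, snp = cand$snp_id[1])
  })
  if (nrow(picks) < n_cis) {
    stop("could not place ", n_cis, " cis effects; only ", nrow(picks),
         " genes have an informative SNP in the window")
  }
  withr::with_seed(as.integer(seed),
                   picks <- picks[sample.int(nrow(picks), n_cis), ])
  picks$beta <- beta
  picks
}

plant_trans <- function(geno, genes, n_trans, beta, cis_effects, seed) {
  withr::with_seed(as.integer(seed), {
    maf <- pmin(colMeans(geno$calls) / 2, 1 - colMeans(geno$calls) / 2)
    variable <- apply(geno$calls, 2, var) > 0
    purrr::map_dfr(seq_len(n_trans), function(k) {
      g <- genes[sample.int(nrow(genes), 1), ]
      cand <- geno$snps[geno$snps$chrom != g$chrom, ]
      cand <- cand[maf[cand$snp_id] >= 0.1 & variable[cand$snp_id], ]
      tibble::tibble(gene = g$gene_id,
                     snp = cand$snp_id[sample.int(nrow(cand), 1)],
                     beta = beta)
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
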