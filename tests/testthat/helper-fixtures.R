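# Hand-built containers for unit tests.

toy_geno <- function(calls, chrom = NULL, pos = NULL, ref = "A", alt = "G",
                     samples = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  snps <- tibble::tibble(
    chrom = if (is.null(chrom)) rep("1", m) else rep_len(chrom, m),
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    ref = rep_len(ref, m), alt = rep_len(alt, m)
  )
  geno_matrix(calls, snps,
              samples = samples %||% paste0("S", seq_len(nrow(calls))))
}

toy_expr <- function(tpm, chrom = NULL, start = NULL, end = NULL,
                     samples = NULL, normalized = NULL) {
  tpm <- as.matrix(tpm)
  g <- nrow(tpm)
  genes <- tibble::tibble(
    gene_id = paste0("g", seq_len(g)),
    chrom = if (is.null(chrom)) rep("1", g) else rep_len(chrom, g),
    start = if (is.null(start)) seq_len(g) * 10000L else start,
    end = if (is.null(end)) seq_len(g) * 10000L + 5000L else end
  )
  expr_matrix(tpm, genes, samples = samples %||% paste0("S", seq_len(ncol(tpm))),
              normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# count tibble row(s) for ASE tests
ase_row <- function(ref_count, alt_count, total_count = ref_count + alt_count,
                    sample = "S1", snp_id = "1:100", chrom = "1", pos = 100L,
                    genotype = 1L) {
  tibble::tibble(sample = sample, snp_id = snp_id, chrom = chrom, pos = pos,
                 ref = "A", alt = "G", ref_count = ref_count,
                 alt_count = alt_count, total_count = total_count,
                 genotype = genotype)
}
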