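---
title: "Methods: eQTL, allele-specific expression and trait integration in an F1 cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL, allele-specific expression and trait integration in an F1 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossexpress)
library(dplyr)
```

# The analysis in one paragraph

crossexpress maps expression quantitative trait loci (eQTL) in a population
of F1 animals from a cross of two divergent founder breeds, corroborates
cis-acting signals with allele-specific expression (ASE) at heterozygous
coding variants, correlates adjusted expression with organismal traits
(here, meat-quality phenotypes), and reports the genes at the intersection
of all three lines of evidence. Because real studies of this kind hinge on
large controlled-access datasets, the package ships a synthetic-data
generator that reproduces the statistical structure the analysis assumes —
an F1 pedigree (8 sires, 158 dams, 189 offspring by default), additive cis
and trans effects on expression, binomial allelic imbalance at
heterozygotes, and planted gene-trait correlations — so every stage can be
validated against known truth.

# Models and procedures

## Genotype quality control

Genotypes are coded 0/1/2 as copies of the alternate allele. QC follows
array-genotyping practice: samples with more than 15% missing calls are
removed first, then SNPs with minor allele frequency below 1% (computed
from non-missing calls only) or more than 10% missing calls. Remaining
missing calls are filled by per-SNP modal imputation with ties broken
toward the lower code — a deliberately simple, fully deterministic fallback
in place of haplotype-based imputation, which is out of scope.

An F1 cross of divergent breeds is expected to violate Hardy-Weinberg
equilibrium wholesale (loci fixed for opposite alleles are 100%
heterozygous), so no HWE test is applied. Extreme genotype distributions
are instead controlled by the genotype-class median rule: per SNP, count
the samples in each of the three genotype classes and keep the SNP iff the
median of the three counts reaches 10% of the sample size
(`ceiling(0.10 * n)`, i.e. 19 of 189). The X chromosome is treated like an
autosome, using codes as provided.

When two genotyping routes are compared (e.g. array calls against variant
calls from RNA-seq reads), SNPs are matched on chromosome, position and
alleles, with automatic detection of reference/alternate swaps (codes
flipped 0&harr;2). Per-sample consistency is the fraction of compared calls
agreeing; heterozygote precision is true-positive heterozygotes over all
heterozygote calls of the test matrix, per SNP and pooled.

## Expression processing

Genes must reach 0.01 TPM in at least 90% of samples (the fraction test is
`count / n >= 0.90`). Each retained gene is then normalized across samples
by a rank-based inverse-normal transform with the Blom offset,
`qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. Rank-based
normalization is stated ambiguously in much of the eQTL literature; we
default to the inverse-normal reading because the downstream linear model
relies on Gaussian residual inference, and provide `rank_only = TRUE` for
the literal centered-ranks alternative. The transform is invariant to any
strictly monotone rescaling of the input, which also means estimated
allele-substitution effects are on the normalized (unit-variance) scale,
not the raw TPM scale.

## The association scan

For every SNP-gene pair the model is

    Y = beta * SNP + PC1..PC5 + sex + batch + boar + age + e

with Y the normalized expression, SNP the 0/1/2 code (so beta is the
allele-substitution effect), the top five genotype principal components
guarding against population stratification, and sex, slaughter batch, boar
(sire) and age as nuisance covariates. Rather than refitting the full
design per pair, the covariates are projected out of both Y and the
genotype columns once (QR residuals); each pair then reduces to a simple
regression with `n - p_cov - 1` residual degrees of freedom. This is
algebraically identical to the per-pair fit (the test suite checks
agreement with per-pair `lm()` to 1e-8) and makes the scan a handful of
matrix products. Monomorphic SNPs are skipped with a warning; a factor
level carried by a single sample is collapsed into the largest level, with
a warning, to keep the design well conditioned.

A pair is **cis** iff the SNP lies within 1 Mb of the gene span
(`[start - 1e6, end + 1e6]`, boundaries inclusive, same chromosome). The
span is strand-agnostic: the usual "TSS to gene end" phrasing is ambiguous
for minus-strand genes, and the span is the superset consistent with the
plus-strand reading. Benjamini-Hochberg adjustment is applied separately
within the cis and the trans sets — the two classes have vastly different
test counts and give distinct p-thresholds at the same q cutoff — with
q <= 0.05 declaring significance.

The genomic inflation factor is the median association chi-square (1 df,
obtained through the two-sided p-values) divided by 0.4549. It is computed
over the pooled set of tests by default; which test set to use is genuinely
open, so the choice is a function argument rather than a constant.

## Heritability of expression

Expression heritability uses the mixed animal model `y = Xb + g + e`,
`g ~ N(0, G sigma_g^2)`, with G the VanRaden method-1 genomic relationship
matrix (`ZZ' / sum(2p(1-p))`) and sex, batch, boar and age as fixed
effects (no principal components — the GRM itself models structure). The
restricted likelihood is profiled in `h2 = sigma_g^2 / (sigma_g^2 +
sigma_e^2)`: one eigendecomposition of the GRM turns the covariance into a
diagonal form, and a bounded scalar search on [0, 1] (tolerance 1e-6) finds
the optimum, with an explicit boundary check at h2 = 0. A 1000-point
grid search of an independently coded dense-solve restricted likelihood
agrees to 0.01 in the tests.

## Linkage disequilibrium

D' and r-squared between two SNPs are computed from unphased genotypes via
the standard EM algorithm over the 3x3 genotype table; the double
heterozygote is the only ambiguous cell. Iteration stops when the largest
haplotype-frequency change falls below 1e-8 (at most 1000 iterations;
non-convergence is an error). Starting at linkage equilibrium is safe here
because the unambiguous cells pull the estimate toward the data in the
first M-step.

## Allele-specific expression

A sample-site record is *informative* when it has at least 10 total reads,
at least 3 allele-specific reads, and each allele exceeds 1% of the total.
The "3 allele-specific reads" rule is read as per-allele (both reference
and alternate need 3 reads), consistent with the companion per-allele 1%
rule; `allele_mode = "total"` implements the laxer summed reading. The
binomial denominator is `ref + alt` — reads carrying third alleles are
excluded, since the test contrasts the two alleles of a biallelic site.

Imbalance is tested per informative site with a two-sided exact binomial
test against a null reference fraction of 0.5 (`min(1, 2 * smaller tail)`,
identical to R's exact test at this symmetric null; the null fraction is
configurable for reference-bias sensitivity analyses, but upstream
N-masked alignment is assumed). FDR is controlled at 5% *within each
sample* — each sample is its own multiple-testing family. At the population
level a SNP is reported only with at least 30 informative heterozygotes of
which at least 10 show significant imbalance; the reported ratio is
`n_ase / n_het`. SNPs are annotated to genes by gene-body overlap
(introns/UTRs included); SNPs in no gene stay unannotated.

The reference allelic-ratio distribution (mean, median, 0.02-wide
histogram, and the fractions above 0.51 / below 0.49) is the residual
mapping-bias diagnostic: symmetric around 0.5 is healthy.

## Trait integration

Both log2 expression (offset 0.25, configurable — the log of zero TPM must
be representable) and each trait are residualized on sex, batch and boar
as fixed effects plus age, and Pearson correlations with two-sided
p-values are computed between the residual vectors; BH is applied within
each trait separately, since each trait is a separate hypothesis family.
The final candidate table takes genes significant in all three analyses,
picking per gene the cis SNP with the lowest q (ties: smaller p, then
lower position) and the ASE SNP with the most heterozygotes (ties: higher
ratio, then lower position); the tie-breaks are not canonical but make the
table deterministic. All eight measured traits (five meat-colour
parameters, two pH measurements, drip loss) are accepted as input, and
reporting follows whatever columns are present.

# The synthetic-data generator

`simulate_study()` inverts the analysis models. Its defaults are the study
conditions: 189 offspring of 8 sires and 158 dams; founder allele
frequencies drawn uniformly per breed unless specified (divergent breeds
arise naturally, and fixation is allowed — it is what makes an F1 cross
heterozygote-rich); covariates with sex over 2 levels, 4 slaughter batches,
boar equal to the sire, and age normal with mean 210 and SD 6 days (sex
ratio and batch count are assumptions, not reported values); negative
binomial read depth with mean 30; residual expression SD 1. Expression is
built as planted additive SNP effects plus covariate effects plus noise;
allele counts at heterozygotes are binomial in the planted reference
fraction theta; each trait with a target correlation r is the mixture
`r * z_gene + sqrt(1 - r^2) * noise`, hitting r in expectation.

Founder haplotypes are drawn independently per SNP, so there is no LD by
default — the simplest structure that exercises every stage. An optional
block mode draws alleles comonotonically within blocks of consecutive SNPs
and transmits parental haplotypes block-wise, giving the strong-LD
configuration needed to exercise the D'/r-squared code. Gene bodies are
anchored to contain at least one SNP, mirroring the fact that variants
called from RNA-seq reads fall inside transcripts; auto-planted cis SNPs
prefer an in-body marker so the same variant can carry both the eQTL and
the ASE signal, as a shared causal regulatory variant would.

What the generator does **not** emulate: realistic LD decay, allele-count
overdispersion beyond the binomial (no beta-binomial), reference mapping
bias, imprinting, copy-number or splicing artefacts, multi-generation
pedigrees, or sequence-level reads. Passing tests therefore demonstrate
correctness of the statistical machinery under the assumed models, not
robustness to every artefact of real RNA-seq data.

Two properties of the F1 design matter when reading the tests. First,
offspring allele frequencies converge to the *realized* founder-pool
frequencies; with only 16 sire haplotypes those deviate visibly from the
configured breed frequencies at single SNPs, so convergence checks are
posed on the signed error averaged over SNPs. Second, planted effects are
defined on the generative scale; rank-inverse-normalization compresses
expression toward unit variance, so estimated betas from the normalized
pipeline are attenuated relative to planted values — detection power is
asserted on the normalized pipeline, effect-size recovery on the
generative scale.

# Numerical choices and degenerate inputs

* Determinism: every generator stage seeds its own stream from the
  configuration seed, so identical configurations are bit-identical and
  stages can be regenerated independently.
* The scan guards `RSS >= 0` against rounding and reports exact-fit pairs
  with p-values below representable precision rather than erroring.
* `rank_inverse_normal()` refuses constant vectors (filter first) and
  propagates NAs.
* `residualize()` refuses rank-deficient designs, naming the aliased
  columns, rather than silently dropping them.
* GRM eigenvalues are clamped at zero after a PSD check with tolerance
  1e-8 relative to the largest eigenvalue.
* Mode-imputation ties go to the lower genotype code; candidate-table ties
  follow the rules above. All tie-breaks are documented and deterministic.

# Problem sizes used in validation

The test suite and the acceptance script validate at deliberately modest
scale, chosen so the whole suite runs in about a minute on one core while
keeping every Monte-Carlo margin comfortable: association-scan oracle
checks at up to 15 SNPs x 15 genes, power replicates at the full n = 189
with 60 SNPs and 6 genes per replicate (50 replicates), heritability
recovery at n = 500 with 600 SNPs (20 replicates), null calibration at
100,000 uniform p-values, 5000 balanced ASE sites, and 2000 null
gene-trait pairs. The statistical properties being checked (unbiasedness,
FDR control, power at planted effect sizes) do not depend on marker count
beyond these scales.

# Known limitations

* The mode-imputation fallback ignores LD entirely; with high missingness
  it biases toward the major genotype.
* The scan is fixed-effects only (as in the MatrixEQTL tradition); the
  mixed model is used solely for heritability. Related individuals
  therefore inflate test statistics slightly — monitor the inflation
  factor.
* `h2` estimates at the [0, 1] boundary have no standard error; none is
  reported.
* ASE testing assumes binomial sampling within a site; true overdispersion
  (technical replicates, allelic mosaicism) would make the per-sample FDR
  anti-conservative.
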