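#' Filter to expressed genes
#'
#' Keeps genes whose TPM reaches `tpm_min` in at least `sample_fraction` of
#' samples, the fraction test being `count / n >= sample_fraction`. With the
#' defaults a gene must reach 0.01 TPM in 90% of samples.
#'
#' @param expr An [expr_matrix()].
#' @param tpm_min Minimum TPM for a gene to count as expressed in a sample
#'   (default 0.01).
#' @param sample_fraction Required fraction of samples (default 0.90).
#' @return The filtered [expr_matrix()]; warns (but does not error) if no
#'   gene survives.
#' @export
filter_expressed_genes <- function(expr, tpm_min = 0.01,
                                   sample_fraction = 0.90) {
  stopifnot(tpm_min > 0, sample_fraction > 0)
  frac <- rowMeans(expr$tpm >= tpm_min)
  keep <- frac >= sample_fraction
  if (!any(keep)) warning("no genes pass the expression filter")
  expr_matrix(expr$tpm[keep, , drop = FALSE], expr$genes[keep, ],
              expr$samples,
              normalized = if (is.null(expr$normalized)) NULL else
                expr$normalized[keep, , drop = FALSE])
}

#' Rank-based inverse-normal transform
#'
#' Maps a vector to normal quantiles of its ranks using the Blom offset:
#' rank r out of n becomes `qnorm((r - 3/8) / (n + 1/4))`. Ties receive
#' average ranks (and therefore equal outputs); the ordering of untied
#' values is preserved exactly, and the result is invariant to any strictly
#' monotone transform of the input. With `rank_only = TRUE` the centered
#' average ranks are returned instead of normal quantiles.
#'
#' @param values Numeric vector with at least 3 finite values, not all
#'   identical.
#' @param rank_only Return centered ranks rather than normal quantiles.
#' @return Numeric vector of the same length; `NA`s propagate.
#' @export
rank_inverse_normal <- function(values, rank_only = FALSE) {
  finite <- is.finite(values)
  x <- values[finite]
  if (length(x) < 3) stop("need at least 3 finite values")
  if (all(x == x[1])) {
    stop("constant vector cannot be rank-normalized; ",
         "filter unexpressed genes first")
  }
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- rep(NA_real_, length(values))
  out[finite] <- if (rank_only) r - (n + 1) / 2 else
    qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Normalize an expression matrix gene by gene
#'
#' Applies [rank_inverse_normal()] to every gene across samples and stores
#' the result in the `normalized` layer.
#'
#' @param expr An [expr_matrix()].
#' @param rank_only Passed to [rank_inverse_normal()].
#' @return The [expr_matrix()] with its `normalized` layer replaced.
#' @export
normalize_expression <- function(expr, rank_only = FALSE) {
  norm <- t(apply(expr$tpm, 1, rank_inverse_normal, rank_only = rank_only))
  expr_matrix(expr$tpm, expr$genes, expr$samples, normalized = norm)
}

# internal: covariate design matrix (intercept + dummies + numeric columns)
covariate_design <- function(covariates,
                             columns = setdiff(names(covariates), "sample")) {
  df <- as.data.frame(covariates[, columns, drop = FALSE])
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  stats::model.matrix(~ ., data = df)
}

#' Residualize a vector on covariates
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus the
#' dummy-coded factors and numeric covariates supplied — the adjustment used
#' before trait-expression correlation (sex, slaughter batch and boar as
#' fixed effects, age as a covariate). Residuals are orthogonal to every
#' design column. A design that is rank deficient even after dropping
#' aliased columns is refused, naming the offending columns.
#'
#' @param values Numeric vector, one element per covariate row.
#' @param covariates Data frame of covariates (a `sample` column, if
#'   present, is ignored).
#' @param columns Covariate columns to use; defaults to all.
#' @return Numeric vector of residuals.
#' @export
residualize <- function(values, covariates,
                        columns = setdiff(names(covariates), "sample")) {
  X <- covariate_design(covariates, columns)
  stopifnot(length(values) == nrow(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  qr.resid(qr_x, values)
}
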