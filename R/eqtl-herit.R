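#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / sum(2 p (1 - p))` where `Z` is the genotype matrix with
#' column means `2p` subtracted and `p` is the observed alternate-allele
#' frequency. Monomorphic SNPs carry no information and are excluded with a
#' warning.
#'
#' @param geno A [geno_matrix()] without missing calls.
#' @return Symmetric n-by-n matrix with sample dimnames.
#' @export
compute_grm <- function(geno) {
  if (anyNA(geno$calls)) stop("missing calls present; impute first")
  p <- colMeans(geno$calls) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic SNPs")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from the GRM")
  }
  Z <- sweep(geno$calls[, poly, drop = FALSE], 2, 2 * p[poly])
  G <- tcrossprod(Z) / sum(2 * p[poly] * (1 - p[poly]))
  dimnames(G) <- list(geno$samples, geno$samples)
  G
}

# internal: eigendecomposition of a GRM, validated PSD
grm_eigen <- function(grm, tol = 1e-8) {
  eig <- eigen(grm, symmetric = TRUE)
  if (min(eig$values) < -tol * max(abs(eig$values), 1)) {
    stop("relationship matrix is not positive semi-definite (eigenvalue ",
         format(min(eig$values)), ")")
  }
  eig$values <- pmax(eig$values, 0)
  eig
}

# internal: restricted log-likelihood of y = Xb + g + e at heritability h2,
# on rotated data (ys = U'y, Xs = U'X, d = eigenvalues of the GRM)
reml_loglik_h2 <- function(h2, ys, Xs, d) {
  n <- length(ys)
  p <- ncol(Xs)
  w <- h2 * d + (1 - h2)
  Xw <- Xs / w
  A <- crossprod(Xs, Xw)
  b <- solve(A, crossprod(Xw, ys))
  r <- ys - Xs %*% b
  rss <- sum(r^2 / w)
  sigma2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(sigma2) + sum(log(w)) +
                       determinant(A, logarithm = TRUE)$modulus +
                       (n - p) + (n - p) * log(2 * pi)))
}

#' REML heritability of an expression trait
#'
#' Fits the mixed animal model `y = Xb + g + e` with `g ~ N(0, G sigma_g^2)`
#' for a genomic relationship matrix `G` and `e ~ N(0, I sigma_e^2)`, and
#' estimates `h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` by restricted
#' maximum likelihood. The GRM is eigendecomposed once, reducing the
#' restricted likelihood to a one-dimensional profile in `h^2` that is
#' maximized by bounded scalar search on `[0, 1]` to tolerance 1e-6. Fixed
#' effects default to sex, slaughter batch and boar plus the age covariate
#' when those columns are present.
#'
#' @param values Numeric vector (normalized expression), one value per
#'   sample.
#' @param grm Genomic relationship matrix from [compute_grm()], or `NULL`
#'   when `eig` is supplied.
#' @param covariates Optional covariate tibble; `NULL` fits intercept only.
#' @param columns Covariate columns to use.
#' @param eig Optional precomputed `eigen()` of the GRM (symmetric), to
#'   amortize the decomposition across many genes.
#' @return An object of class `herit_fit`: list with `h2`, `sigma_g2`,
#'   `sigma_e2`, `loglik`, `n`. Has [tidy()] and [glance()] methods.
#' @export
reml_heritability <- function(values, grm, covariates = NULL,
                              columns = intersect(c("sex", "batch", "boar",
                                                    "age"),
                                                  names(covariates)),
                              eig = NULL) {
  if (is.null(eig)) eig <- grm_eigen(grm)
  n <- length(values)
  stopifnot(length(eig$values) == n)
  X <- if (is.null(covariates) || length(columns) == 0) {
    matrix(1, n, 1)
  } else {
    covariate_design(collapse_degenerate_levels(covariates), columns)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  ys <- crossprod(eig$vectors, values)
  Xs <- crossprod(eig$vectors, X)
  d <- eig$values
  obj <- function(h2) reml_loglik_h2(h2, ys, Xs, d)
  opt <- optimize(obj, interval = c(0, 1 - 1e-9), maximum = TRUE,
                  tol = 1e-6)
  h2 <- opt$maximum
  # boundary polish: the interior optimum can sit at the edge
  if (obj(0) >= opt$objective) h2 <- 0
  w <- h2 * d + (1 - h2)
  Xw <- Xs / w
  A <- crossprod(Xs, Xw)
  b <- solve(A, crossprod(Xw, ys))
  rss <- sum((ys - Xs %*% b)^2 / w)
  sigma2 <- rss / (n - ncol(Xs))
  structure(
    list(h2 = h2, sigma_g2 = h2 * sigma2, sigma_e2 = (1 - h2) * sigma2,
         loglik = if (h2 == 0) obj(0) else opt$objective, n = n),
    class = "herit_fit"
  )
}

#' @export
print.herit_fit <- function(x, ...) {
  cat(sprintf(
    "<herit_fit> h2 = %.3f (sigma_g2 = %.3f, sigma_e2 = %.3f), REML loglik = %.2f, n = %d\n",
    x$h2, x$sigma_g2, x$sigma_e2, x$loglik, x$n
  ))
  invisible(x)
}

#' Heritability of every gene in an expression matrix
#'
#' Convenience wrapper running [reml_heritability()] gene by gene with a
#' single GRM eigendecomposition.
#'
#' @param expr An [expr_matrix()] with a normalized layer.
#' @param grm Genomic relationship matrix.
#' @param covariates Optional covariate tibble.
#' @return Tibble with `gene`, `h2`, `sigma_g2`, `sigma_e2`, `loglik`.
#' @export
heritability_scan <- function(expr, grm, covariates = NULL) {
  if (is.null(expr$normalized)) stop("normalize the expression matrix first")
  eig <- grm_eigen(grm)
  purrr::map_dfr(rownames(expr$normalized), function(g) {
    fit <- reml_heritability(expr$normalized[g, ], grm = NULL,
                             covariates = covariates, eig = eig)
    tibble::tibble(gene = g, h2 = fit$h2, sigma_g2 = fit$sigma_g2,
                   sigma_e2 = fit$sigma_e2, loglik = fit$loglik)
  })
}
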