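# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# per-pair full-design OLS for the association scan
oracle_scan <- function(geno, expr, covariates = NULL) {
  out <- list()
  C <- if (is.null(covariates)) NULL else
    as.data.frame(covariates[setdiff(names(covariates), "sample")])
  for (s in geno$snps$snp_id) {
    for (g in rownames(expr$normalized)) {
      df <- data.frame(y = expr$normalized[g, ], snp = geno$calls[, s])
      if (!is.null(C)) df <- cbind(df, C)
      fit <- summary(lm(y ~ ., data = df))$coefficients
      out[[length(out) + 1]] <- tibble::tibble(
        snp_id = s, gene = g, beta = fit["snp", 1], tstat = fit["snp", 3],
        p = fit["snp", 4]
      )
    }
  }
  dplyr::bind_rows(out)
}

# two-sided exact binomial p at theta = 0.5 by full pmf enumeration
oracle_binom_p <- function(k, n) {
  pmf <- vapply(0:n, function(j) choose(n, j) / 2^n, numeric(1))
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# dense-solve restricted log-likelihood, profiled over the total variance;
# same convention as the package (includes its constants) but computed via
# solve() on the full covariance rather than an eigendecomposition
oracle_reml_loglik <- function(h2, y, K, Xmat) {
  n <- length(y)
  p <- ncol(Xmat)
  V <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V)
  XtViX <- t(Xmat) %*% Vi %*% Xmat
  b <- solve(XtViX, t(Xmat) %*% Vi %*% y)
  r <- y - Xmat %*% b
  rss <- as.numeric(t(r) %*% Vi %*% r)
  sigma2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(sigma2) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       (n - p) + (n - p) * log(2 * pi)))
}

oracle_reml_grid <- function(y, K, Xmat,
                             grid = seq(0, 0.999, length.out = 1000)) {
  ll <- vapply(grid, oracle_reml_loglik, numeric(1), y = y, K = K,
               Xmat = Xmat)
  grid[which.max(ll)]
}

# step-up BH by its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}
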