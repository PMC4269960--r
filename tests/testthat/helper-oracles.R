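# Independent brute-force oracles used to pin the numerical engines.
# These deliberately use plain loops and explicit dense inverses, not the
# package's vectorised/spectral code paths.

# Exhaustive KNN imputation: enumerate all pairwise overlap-scaled Euclidean
# distances and neighbour lists cell by cell.
oracle_knn_impute <- function(X, k) {
  n <- nrow(X); m <- ncol(X)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    sh <- which(!is.na(X[i, ]) & !is.na(X[j, ]))
    if (length(sh) > 0L)
      D[i, j] <- sqrt(sum((X[i, sh] - X[j, sh])^2) * m / length(sh))
  }
  out <- X
  for (i in seq_len(n)) for (j in seq_len(m)) if (is.na(X[i, j])) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[is.finite(D[i, ord])]
    donors <- ord[!is.na(X[ord, j])]
    out[i, j] <- if (length(donors) == 0L) mean(X[, j], na.rm = TRUE)
                 else mean(X[utils::head(donors, k), j])
  }
  out
}

# Dense-matrix restricted log-likelihood with explicit inverses and
# determinants (differs from the spectral criterion by the constant
# -log(n)/2, which cancels in comparisons across lambda).
oracle_dense_reml <- function(K, y, lambda) {
  n <- length(y)
  X <- matrix(1, n, 1L)
  H <- K + lambda * diag(n)
  Hi <- solve(H)
  XtHiX <- drop(crossprod(X, Hi %*% X))
  P <- Hi - (Hi %*% X %*% crossprod(X, Hi)) / XtHiX
  s2 <- drop(crossprod(y, P %*% y)) / (n - 1L)
  -0.5 * ((n - 1L) * log(2 * pi * s2) +
            as.numeric(determinant(H)$modulus) + log(XtHiX) + (n - 1L))
}

oracle_reml_grid <- function(K, y, n_points = 2001L) {
  grid <- seq(-20, 20, length.out = n_points)
  vals <- vapply(grid, function(g) oracle_dense_reml(K, y, exp(g)), numeric(1))
  list(grid = grid, values = vals,
       loglambda_hat = grid[which.max(vals)], max = max(vals))
}

# Small complete genotype matrix with ids, for tests that need a fixture.
toy_genotypes <- function(n, m, seed = 1L, encoding = "ZERO_1_2") {
  set.seed(seed)
  lo <- if (encoding == "MINUS1_0_1") -1L else 0L
  M <- matrix(sample(lo:(lo + 2L), n * m, replace = TRUE), n, m,
              dimnames = list(paste0("ind", seq_len(n)),
                              paste0("mk", seq_len(m))))
  genotype_matrix(M, encoding)
}

write_genotype_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
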