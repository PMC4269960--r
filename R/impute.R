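#' K-nearest-neighbour imputation of missing marker dosages
#'
#' Each missing cell (i, j) is replaced by the mean dosage at marker j among
#' the k individuals nearest to i. Distance between two individuals is the
#' Euclidean distance over markers observed in both, scaled by
#' `sqrt(m / m_shared)` to correct for differing overlap. Neighbours that are
#' themselves missing at marker j are skipped in favour of the next nearest;
#' if no neighbour has data at j the column mean is used. Distance ties break
#' by ascending row index, so the result is deterministic. Non-missing cells
#' are never changed.
#'
#' Distances are computed from the observed data only, so the operation is
#' idempotent, and every imputed value lies within the observed dosage range
#' of its marker. A matrix with no missing cells is returned unchanged;
#' otherwise the output encoding is `CONTINUOUS` (neighbour means need not be
#' integers).
#'
#' @param g a [genotype_matrix].
#' @param k number of neighbours (default 5).
#' @return a complete [genotype_matrix].
#' @export
knn_impute <- function(g, k = 5L) {
  if (k < 1L) stop("'k' must be a positive integer")
  X <- g$dosage
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("KNN imputation requires at least 2 individuals")
  obs <- !is.na(X)
  if (!any(!obs)) return(g)

  all_missing <- colSums(obs) == 0L
  if (any(all_missing))
    stop("marker missing in all individuals: ",
         colnames(X)[which(all_missing)[1L]])

  # Pairwise squared distances over shared markers, via cross-products on the
  # zero-filled matrix (missing entries contribute nothing).
  Z <- X; Z[!obs] <- 0
  O <- obs * 1
  Z2 <- Z * Z
  shared <- tcrossprod(O)                       # counts of jointly observed markers
  ss <- tcrossprod(Z2, O) + tcrossprod(O, Z2) - 2 * tcrossprod(Z)
  ss <- pmax(ss, 0)

  isolated <- vapply(seq_len(n), function(i)
    all(shared[i, -i] == 0L), logical(1))
  if (any(isolated))
    stop("individual shares no observed markers with any other individual: ",
         rownames(X)[which(isolated)[1L]])

  D <- sqrt(ss * (m / pmax(shared, 1L)))
  D[shared == 0L] <- Inf
  diag(D) <- Inf

  col_means <- colSums(Z) / colSums(O)
  out <- X
  for (i in which(rowSums(!obs) > 0L)) {
    ord <- order(D[i, ], seq_len(n))            # ties by ascending row index
    ord <- ord[is.finite(D[i, ord])]
    for (j in which(!obs[i, ])) {
      donors <- ord[obs[ord, j]]
      if (length(donors) == 0L) {
        out[i, j] <- col_means[j]
      } else {
        out[i, j] <- mean(X[utils::head(donors, k), j])
      }
    }
  }
  base <- if (g$encoding == "CONTINUOUS") g$base_encoding else g$encoding
  genotype_matrix(out, "CONTINUOUS", base_encoding = base)
}

#' Per-marker summary statistics
#'
#' Allele frequencies are computed on the {0,1,2} dosage scale (frequency of
#' the counted allele = mean dosage / 2), over non-missing entries only.
#'
#' @param g a [genotype_matrix].
#' @return data.frame with columns `marker`, `allele_frequency`,
#'   `missing_rate`, `monomorphic`.
#' @export
marker_summaries <- function(g) {
  M <- dosage_012(g)
  n <- nrow(M)
  p <- colMeans(M, na.rm = TRUE) / 2
  miss <- colSums(is.na(M)) / n
  mono <- apply(M, 2L, function(col) {
    v <- col[!is.na(col)]
    length(v) == 0L || all(v == v[1L])
  })
  data.frame(marker = colnames(M), allele_frequency = unname(p),
             missing_rate = unname(miss), monomorphic = unname(mono),
             row.names = NULL, stringsAsFactors = FALSE)
}
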