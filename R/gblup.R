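#' Realized additive relationship matrix
#'
#' VanRaden-style genomic kinship from marker dosages. Dosages are taken on
#' the {0,1,2} scale; for each polymorphic marker j the allele frequency
#' p_j is computed and the centered matrix W has entries `w_ij = m_ij - 2 p_j`.
#' With the scale constant `c = 2 * sum_j p_j (1 - p_j)`,
#' `K = W W' / c`. Monomorphic markers carry no relationship information and
#' are excluded from both W and c.
#'
#' Because the centering frequencies come from the same matrix, every column
#' of W sums to zero, so K annihilates the vector of ones: under the GBLUP
#' model the GLS estimate of the population mean is then the arithmetic mean
#' and the GEBVs sum to zero.
#'
#' @param g a complete [genotype_matrix] (impute first if needed), n >= 2.
#' @return object of class `kinship_matrix`: list with `K` (symmetric n x n,
#'   dimnames = individual ids), `centering_frequencies` (named by marker),
#'   and `scale_constant`.
#' @export
kinship_matrix <- function(g) {
  M <- dosage_012(g)
  if (anyNA(M))
    stop("genotype matrix has missing cells; run knn_impute() first")
  if (nrow(M) < 2L)
    stop("kinship requires at least 2 individuals")
  p <- colMeans(M) / 2
  poly <- apply(M, 2L, function(col) any(col != col[1L]))
  if (!any(poly))
    stop("degenerate genotypes: all markers are monomorphic")
  W <- sweep(M[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  cc <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / cc
  K <- (K + t(K)) / 2
  structure(list(K = K, centering_frequencies = p[poly], scale_constant = cc),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d individuals, %d markers, mean diagonal %.3f\n",
              nrow(x$K), length(x$centering_frequencies), mean(diag(x$K))))
  invisible(x)
}

#' Restricted log-likelihood of the variance ratio
#'
#' Profile restricted log-likelihood of the GBLUP model
#' `y = mu + g + e`, `g ~ N(0, K sg2)`, `e ~ N(0, I se2)`, parameterised by
#' `lambda = se2 / sg2`, after projecting the intercept out and rotating into
#' the eigenbasis of the projected kinship. With eigenvalues `xi_i` and
#' rotated responses `eta_i` (i = 1..n-1),
#' `l_R(lambda) = -1/2 * ((n-1) log(2 pi sg2_hat) + sum_i log(xi_i + lambda) + (n-1))`
#' where `sg2_hat = mean(eta_i^2 / (xi_i + lambda))`.
#'
#' @param lambda positive variance ratio se2/sg2.
#' @param eigenvalues eigenvalues of the intercept-projected kinship (length n-1).
#' @param rotated_y responses rotated into the corresponding eigenbasis.
#' @return scalar restricted log-likelihood.
#' @export
restricted_log_likelihood <- function(lambda, eigenvalues, rotated_y) {
  if (!is.finite(lambda) || lambda <= 0)
    stop("'lambda' must be a positive finite variance ratio")
  q <- length(eigenvalues)
  stopifnot(length(rotated_y) == q)
  d <- eigenvalues + lambda
  sg2 <- mean(rotated_y^2 / d)
  -0.5 * (q * log(2 * pi * sg2) + sum(log(d)) + q)
}

# Eigen-structure of K projected orthogonally to the intercept:
# an orthonormal basis of 1-perp, the projected eigenvalues (clipped to >= 0),
# and the rotation needed for the spectral REML criterion.
project_kinship <- function(K) {
  n <- nrow(K)
  Q2 <- qr.Q(qr(matrix(1, n, 1L)), complete = TRUE)[, -1L, drop = FALSE]
  e <- eigen(crossprod(Q2, K %*% Q2), symmetric = TRUE)
  xi <- pmax(e$values, 0)   # clip small negative PSD noise
  list(U = Q2 %*% e$vectors, xi = xi)
}

#' Fit the GBLUP mixed model by REML
#'
#' Maximises the restricted log-likelihood over `log(lambda)` in `[-20, 20]`
#' by bounded 1-D optimisation (tolerance 1e-8) using one spectral
#' decomposition of the intercept-projected kinship, then recovers the
#' variance components, the GLS population mean, the GEBVs
#' `g_hat = K (K + lambda I)^-1 (y - mu)`, residuals, and narrow-sense
#' heritability `h2 = sg2 / (sg2 + se2)`.
#'
#' @param y an [adjusted_phenotypes] or a named numeric vector of phenotype
#'   values (names = genotype ids present in `K`).
#' @param K a [kinship_matrix].
#' @return object of class `gblup_fit` with components `mu`, `sigma_g2`,
#'   `sigma_e2`, `lambda`, `gebvs`, `residuals`, `h2`, `reml_loglik`,
#'   `boundary` (TRUE when the optimum sits at a search bound), `alpha`
#'   (the solution `(K + lambda I)^-1 (y - mu)`, reused for marker effects)
#'   and `individual_ids`.
#' @export
fit_gblup <- function(y, K) {
  yv <- pheno_values(y)
  ids <- names(yv)
  absent <- setdiff(ids, rownames(K$K))
  if (length(absent) == length(ids))
    stop("alignment error: no phenotyped genotype is present in the kinship matrix")
  if (length(absent)) {
    warning(length(absent), " phenotyped genotype(s) lack genotypes and are dropped: ",
            paste(utils::head(absent, 5L), collapse = ", "))
    ids <- setdiff(ids, absent)
    yv <- yv[ids]
  }
  n <- length(ids)
  if (n < 3L)
    stop("GBLUP requires at least 3 individuals with phenotypes and genotypes")
  Kmat <- K$K[ids, ids, drop = FALSE]

  proj <- project_kinship(Kmat)
  eta <- drop(crossprod(proj$U, yv))

  obj <- function(loglam) restricted_log_likelihood(exp(loglam), proj$xi, eta)
  opt <- stats::optimize(obj, interval = c(-20, 20), maximum = TRUE,
                         tol = 1e-8)
  if (!is.finite(opt$objective))
    stop("restricted likelihood is not finite; check the phenotypes")
  lambda <- exp(opt$maximum)
  boundary <- opt$maximum < -20 + 1e-4 || opt$maximum > 20 - 1e-4

  sigma_g2 <- mean(eta^2 / (proj$xi + lambda))
  sigma_e2 <- lambda * sigma_g2
  h2 <- sigma_g2 / (sigma_g2 + sigma_e2)

  eK <- eigen(Kmat, symmetric = TRUE)
  d <- pmax(eK$values, 0) + lambda
  Uy <- crossprod(eK$vectors, yv)
  U1 <- crossprod(eK$vectors, rep(1, n))
  mu <- sum(U1 * Uy / d) / sum(U1 * U1 / d)
  alpha <- drop(eK$vectors %*% ((Uy - mu * U1) / d))
  gebvs <- drop(Kmat %*% alpha)
  names(alpha) <- names(gebvs) <- ids
  resid <- yv - mu - gebvs

  structure(list(mu = mu, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 lambda = lambda, gebvs = gebvs, residuals = resid,
                 h2 = h2, reml_loglik = opt$objective, boundary = boundary,
                 alpha = alpha, individual_ids = ids),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gblup_fit: n = %d\n", length(x$individual_ids)))
  cat(sprintf("  mu = %.4f, sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$mu, x$sigma_g2, x$sigma_e2, x$h2))
  cat(sprintf("  REML log-likelihood = %.4f%s\n", x$reml_loglik,
              if (isTRUE(x$boundary)) " (variance ratio at search boundary)" else ""))
  invisible(x)
}

#' Back-solve additive marker effects from a GBLUP fit
#'
#' Under the ridge-regression (RR-BLUP) parameterisation the marker effects
#' are `u_hat = (1/c) W' (K + lambda I)^-1 (y - mu)`, using the same centered
#' matrix W, scale constant c and centering frequencies as the kinship. The
#' identity `W u_hat = g_hat` holds exactly, so GEBVs may equivalently be
#' computed as dosage-weighted sums of marker effects — the route used to
#' predict unphenotyped selection candidates.
#'
#' @param fit a [fit_gblup] result.
#' @param g the [genotype_matrix] the kinship was built from.
#' @param K the [kinship_matrix] used in the fit.
#' @return object of class `marker_effects`: list with `effects` (named by
#'   marker; monomorphic markers excluded), `centering_frequencies`, and
#'   `scale_constant`.
#' @export
marker_effects <- function(fit, g, K) {
  if (is.null(K$centering_frequencies))
    stop("kinship matrix lacks centering frequencies")
  mk <- names(K$centering_frequencies)
  M <- dosage_012(subset_genotypes(g, individuals = fit$individual_ids,
                                   markers = mk))
  W <- sweep(M, 2L, 2 * K$centering_frequencies, "-")
  u <- drop(crossprod(W, fit$alpha)) / K$scale_constant
  names(u) <- mk
  structure(list(effects = u,
                 centering_frequencies = K$centering_frequencies,
                 scale_constant = K$scale_constant),
            class = "marker_effects")
}

#' Serialise a GBLUP fit
#'
#' Scalars go to JSON; GEBVs to a TSV sorted by descending value (ties by
#' genotype name).
#'
#' @param fit a `gblup_fit`.
#' @param json_path,tsv_path output paths (NULL to skip either).
#' @export
write_gblup_fit <- function(fit, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    scalars <- list(mu = fit$mu, sigma_g2 = fit$sigma_g2,
                    sigma_e2 = fit$sigma_e2, lambda = fit$lambda,
                    h2 = fit$h2, reml_loglik = fit$reml_loglik,
                    boundary = fit$boundary,
                    n_individuals = length(fit$individual_ids))
    jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(genotype = names(fit$gebvs), gebv = unname(fit$gebvs))
    df <- df[order(-df$gebv, df$genotype), , drop = FALSE]
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fit)
}

#' @rdname write_gblup_fit
#' @param eff a `marker_effects`.
#' @param path output TSV path; columns marker, effect, centering_frequency.
#' @export
write_marker_effects <- function(eff, path) {
  df <- data.frame(marker = names(eff$effects), effect = unname(eff$effects),
                   centering_frequency = unname(eff$centering_frequencies))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
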