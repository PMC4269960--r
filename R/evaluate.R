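# Evaluate an expression under a temporary RNG state so that seeded helpers
# never disturb the caller's random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' k-fold cross-validation of genomic prediction accuracy
#'
#' The training set is randomly divided into k folds of near-equal size
#' (sizes differ by at most 1). For each fold, the full pipeline is refit on
#' the remaining folds only — kinship, centering allele frequencies, REML
#' variance components and marker effects all come from the training folds,
#' so no information leaks from the held-out individuals — and the held-out
#' GEBVs are predicted through the marker-effects route. The fold's accuracy
#' is the Pearson correlation between predicted GEBVs and the held-out
#' observed (adjusted) phenotypes; the model accuracy is the mean over folds.
#'
#' A fold whose observed or predicted values have zero variance yields an
#' undefined correlation; it is recorded as `NA` and excluded from the mean,
#' with a warning.
#'
#' @param y an [adjusted_phenotypes] or named numeric vector.
#' @param g a complete [genotype_matrix] containing every phenotyped
#'   individual.
#' @param k number of folds (default 10).
#' @param seed integer seed driving the fold partition.
#' @return object of class `cv_result`: list with `k`, `seed`,
#'   `fold_assignment` (named integer vector), `fold_correlations`, and
#'   `accuracy` (mean of the defined fold correlations).
#' @export
k_fold_cross_validate <- function(y, g, k = 10L, seed = 1L) {
  yv <- pheno_values(y)
  ids <- names(yv)
  if (k < 2L) stop("'k' must be at least 2")
  n <- length(ids)
  if (n < 2L * k)
    stop("cross-validation needs at least 2k individuals (n = ", n,
         ", k = ", k, ")")
  if (n %/% k < 3L)
    stop("folds would have fewer than 3 individuals; use a smaller k")
  absent <- setdiff(ids, individuals(g))
  if (length(absent))
    stop("phenotyped individuals absent from genotype matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  if (anyNA(g$dosage))
    stop("genotype matrix has missing cells; run knn_impute() first")

  fold <- with_seed(seed, {
    stats::setNames(rep(seq_len(k), length.out = n)[order(stats::runif(n))], ids)
  })

  rs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test_ids <- ids[fold == f]
    train_ids <- ids[fold != f]
    K_tr <- kinship_matrix(subset_genotypes(g, individuals = train_ids))
    fit <- fit_gblup(yv[train_ids], K_tr)
    eff <- marker_effects(fit, g, K_tr)
    pred <- predict_candidates(fit, eff,
                               subset_genotypes(g, individuals = test_ids))
    obs <- yv[test_ids]
    if (stats::sd(obs) == 0 || stats::sd(pred[test_ids]) == 0) {
      warning("fold ", f, " has zero variance; its correlation is undefined ",
              "and excluded from the accuracy")
    } else {
      rs[f] <- stats::cor(pred[test_ids], obs)
    }
  }
  structure(list(k = k, seed = seed, fold_assignment = fold,
                 fold_correlations = rs,
                 accuracy = mean(rs, na.rm = TRUE)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold, seed %d, accuracy %.3f\n",
              x$k, x$seed, x$accuracy))
  invisible(x)
}

#' Phenotypic correlations between traits
#'
#' Pearson correlations between adjusted phenotypes, computed on
#' pairwise-complete genotypes. Pairs with fewer than 3 shared genotypes are
#' reported as `NA`.
#'
#' @param parts named list of [adjusted_phenotypes], one per trait (at least
#'   2); names default to the traits recorded in each element.
#' @return object of class `correlation_matrix`: list with `traits`,
#'   `r` (symmetric, unit diagonal) and `n_pairs` (pairwise-complete counts).
#' @export
trait_correlations <- function(parts) {
  if (length(parts) < 2L)
    stop("trait correlations require at least 2 traits")
  traits <- names(parts)
  if (is.null(traits))
    traits <- vapply(parts, function(x) x$trait, character(1))
  genos <- sort(unique(unlist(lapply(parts, function(x) names(pheno_values(x))))))
  mat <- matrix(NA_real_, length(genos), length(traits),
                dimnames = list(genos, traits))
  for (j in seq_along(parts)) {
    v <- pheno_values(parts[[j]])
    mat[names(v), j] <- v
  }
  n_pairs <- crossprod(!is.na(mat))
  suppressWarnings(r <- stats::cor(mat, use = "pairwise.complete.obs"))
  r[n_pairs < 3L] <- NA_real_
  diag(r) <- 1
  structure(list(traits = traits, r = r, n_pairs = n_pairs),
            class = "correlation_matrix")
}

#' @rdname trait_correlations
#' @param x a `correlation_matrix`.
#' @param path output TSV path (square matrix with trait header row/column).
#' @export
write_correlation_matrix <- function(x, path) {
  df <- data.frame(trait = x$traits, x$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics of adjusted phenotypes
#'
#' @param y an [adjusted_phenotypes] or named numeric vector.
#' @return one-row data.frame: count, mean, sd (n-1 denominator; `NA` for a
#'   single value), min, median, max.
#' @export
descriptive_stats <- function(y) {
  v <- pheno_values(y)
  if (length(v) == 0L) stop("no phenotype values")
  data.frame(count = length(v), mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
             min = min(v), median = stats::median(v), max = max(v))
}
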