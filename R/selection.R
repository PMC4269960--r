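#' Predict GEBVs of selection candidates
#'
#' Candidate dosages are centered with the training population's allele
#' frequencies (`w = m - 2 p_train`) over the markers shared with the
#' training set, and the GEBV is the dosage-weighted sum of the trained
#' marker effects, `w %*% u_hat`. Candidates never enter the training fit.
#' Effects of training markers absent from the candidates are dropped
#' without rescaling; a warning reports any partial overlap.
#'
#' @param fit a [fit_gblup] result (unused beyond validation; retained so the
#'   prediction is explicitly tied to a trained model).
#' @param eff the [marker_effects] of the trained model.
#' @param cand a complete [genotype_matrix] of candidates, ideally already
#'   restricted via [match_markers()].
#' @return named numeric vector of GEBVs, one per candidate, in candidate
#'   row order.
#' @export
predict_candidates <- function(fit, eff, cand) {
  if (anyNA(cand$dosage))
    stop("candidate genotypes have missing cells; run knn_impute() first")
  train_mk <- names(eff$effects)
  shared <- train_mk[train_mk %in% markers(cand)]
  if (length(shared) == 0L)
    stop("incompatible populations: no shared markers between model and candidates")
  if (length(shared) < length(train_mk))
    warning(sprintf("candidates cover %d of %d model markers (overlap %.3f); ",
                    length(shared), length(train_mk),
                    length(shared) / length(train_mk)),
            "absent markers are dropped from the prediction")
  M <- dosage_012(subset_genotypes(cand, markers = shared))
  W <- sweep(M, 2L, 2 * eff$centering_frequencies[shared], "-")
  drop(W %*% eff$effects[shared])
}

#' Multi-trait selection index
#'
#' Ranks individuals by a weighted linear combination of their per-trait
#' GEBVs: `index_i = sum_t w_t * GEBV_it`, over the genotypes that have a
#' GEBV for every weighted trait. By default GEBVs enter on their raw scale;
#' `standardize = TRUE` z-scores each trait's GEBVs first, for traits
#' measured on incommensurate scales.
#'
#' @param gebv_tables named list (by trait) of named numeric GEBV vectors.
#' @param weights named numeric vector of trait weights.
#' @param standardize z-score each trait's GEBVs before weighting.
#' @return object of class `selection_index_result`: list with `weights`,
#'   `index` (named, sorted descending, ties by genotype name) and
#'   `traits_used`.
#' @export
selection_index <- function(gebv_tables, weights, standardize = FALSE) {
  if (length(weights) == 0L || is.null(names(weights)))
    stop("'weights' must be a non-empty named numeric vector")
  absent <- setdiff(names(weights), names(gebv_tables))
  if (length(absent))
    stop("no GEBV table for weighted trait(s): ", paste(absent, collapse = ", "))
  traits <- names(weights)
  genos <- Reduce(intersect, lapply(gebv_tables[traits], names))
  if (length(genos) == 0L)
    stop("no genotype has GEBVs for every weighted trait")
  idx <- stats::setNames(numeric(length(genos)), genos)
  for (tr in traits) {
    v <- gebv_tables[[tr]][genos]
    if (standardize) {
      s <- stats::sd(v)
      v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
    idx <- idx + weights[[tr]] * v
  }
  idx <- idx[order(-idx, names(idx))]
  structure(list(weights = weights, index = idx, traits_used = traits),
            class = "selection_index_result")
}

#' @export
print.selection_index_result <- function(x, ...) {
  cat(sprintf("selection_index_result: %d genotypes, traits %s\n",
              length(x$index), paste(x$traits_used, collapse = ", ")))
  print(utils::head(round(x$index, 4), 10L))
  invisible(x)
}

#' Write a ranking (GEBVs or selection index) to TSV
#'
#' Columns genotype, value; sorted by descending value, ties by genotype
#' name, so outputs are deterministic and diffable.
#'
#' @param values named numeric vector.
#' @param path output TSV path.
#' @param value_name header for the value column.
#' @export
write_ranking <- function(values, path, value_name = "value") {
  df <- data.frame(genotype = names(values), value = unname(values))
  df <- df[order(-df$value, df$genotype), , drop = FALSE]
  names(df)[2L] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
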