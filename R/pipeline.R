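#' Train genomic prediction models from genotype and phenotype files
#'
#' End-to-end training mirroring the breeder's workflow: assemble the
#' training population from one or more trials (adjust phenotypes within
#' each trial, then average genotype values across trials), impute missing
#' marker dosages, build the realized relationship matrix, fit the GBLUP
#' model by REML, back-solve marker effects, and estimate accuracy by
#' k-fold cross-validation. One model is fit per trait; multi-trait runs
#' additionally report the phenotypic trait correlation matrix and a model
#' summary table (trait, accuracy, heritability).
#'
#' Per trait the run writes six files into `out_dir`:
#' `<trait>_adjusted_phenotypes.tsv`, `<trait>_model.json`,
#' `<trait>_gebvs.tsv`, `<trait>_marker_effects.tsv`, `<trait>_cv.json`,
#' `<trait>_stats.tsv`; plus `model_summary.tsv`, `correlation_matrix.tsv`
#' (multi-trait only) and a machine-readable `provenance.json` sufficient to
#' re-execute the run.
#'
#' @param genotype_file training genotype TSV.
#' @param phenotype_file plot-level phenotype CSV.
#' @param out_dir output directory (created if needed).
#' @param traits traits to model; default: all traits phenotyped in every
#'   selected trial.
#' @param trials trials to combine; default: all trials in the file.
#' @param list_file optional list file restricting the training individuals.
#' @param k cross-validation folds (default 10).
#' @param seed integer seed for the CV partition.
#' @param knn_k neighbours for KNN imputation (default 5).
#' @param impute impute missing dosages (default TRUE); with `FALSE`,
#'   missing dosages are an error.
#' @return (invisibly) named list per trait with components `y`, `fit`,
#'   `effects`, `cv`.
#' @export
run_train <- function(genotype_file, phenotype_file, out_dir,
                      traits = NULL, trials = NULL, list_file = NULL,
                      k = 10L, seed = 1L, knn_k = 5L, impute = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- read_genotype_matrix(genotype_file)
  p <- read_phenotype_table(phenotype_file)

  if (!is.null(list_file)) {
    keep <- read_individual_list(list_file)
    p <- phenotype_table(as.data.frame(p)[p$genotype %in% keep, , drop = FALSE])
    g <- subset_genotypes(g, individuals = intersect(individuals(g), keep))
  }
  if (is.null(trials)) trials <- unique(p$trial)
  bad_trials <- setdiff(trials, unique(p$trial))
  if (length(bad_trials))
    stop("unknown trial(s): ", paste(bad_trials, collapse = ", "),
         "; available: ", paste(unique(p$trial), collapse = ", "))
  subtables <- lapply(trials, function(tr)
    phenotype_table(as.data.frame(p)[p$trial == tr, , drop = FALSE]))
  if (is.null(traits)) traits <- common_traits(subtables)
  bad_traits <- setdiff(traits, trait_names(p))
  if (length(bad_traits))
    stop("unknown trait(s): ", paste(bad_traits, collapse = ", "),
         "; available: ", paste(trait_names(p), collapse = ", "))
  if (length(traits) == 0L)
    stop("no trait is phenotyped in every selected trial")

  if (anyNA(g$dosage)) {
    if (!impute)
      stop("genotype matrix has missing cells and imputation is disabled")
    g <- knn_impute(g, knn_k)
  }

  results <- list()
  adjusted <- list()
  for (trait in traits) {
    with_data <- trials[vapply(trials, function(tr)
      any(!is.na(p[[trait]][p$trial == tr])), logical(1))]
    parts <- lapply(with_data, function(tr) adjust_single_trial(p, trait, tr))
    y <- if (length(parts) > 1L) combine_trials(parts) else parts[[1L]]
    ids <- intersect(names(y$values), individuals(g))
    if (length(ids) < 3L)
      stop("fewer than 3 genotyped+phenotyped individuals for trait '",
           trait, "'")
    yv <- y$values[ids]
    g_tr <- subset_genotypes(g, individuals = ids)
    K <- kinship_matrix(g_tr)
    fit <- fit_gblup(yv, K)
    eff <- marker_effects(fit, g_tr, K)
    cv <- k_fold_cross_validate(yv, g_tr, k = k, seed = seed)

    pre <- file.path(out_dir, trait)
    write_adjusted_phenotypes(y, paste0(pre, "_adjusted_phenotypes.tsv"))
    write_gblup_fit(fit, json_path = paste0(pre, "_model.json"),
                    tsv_path = paste0(pre, "_gebvs.tsv"))
    write_marker_effects(eff, paste0(pre, "_marker_effects.tsv"))
    jsonlite::write_json(list(k = cv$k, seed = cv$seed,
                              fold_assignment = as.list(cv$fold_assignment),
                              fold_correlations = cv$fold_correlations,
                              accuracy = cv$accuracy),
                         paste0(pre, "_cv.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    utils::write.table(descriptive_stats(yv), paste0(pre, "_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    adjusted[[trait]] <- y
    results[[trait]] <- list(y = y, fit = fit, effects = eff, cv = cv)
  }

  summary_df <- data.frame(
    trait = traits,
    accuracy = vapply(results, function(r) r$cv$accuracy, numeric(1)),
    h2 = vapply(results, function(r) r$fit$h2, numeric(1)),
    row.names = NULL)
  utils::write.table(summary_df, file.path(out_dir, "model_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(traits) > 1L)
    write_correlation_matrix(trait_correlations(adjusted),
                             file.path(out_dir, "correlation_matrix.tsv"))

  write_provenance(out_dir, command = "train",
                   inputs = list(genotype_file = genotype_file,
                                 phenotype_file = phenotype_file,
                                 list_file = list_file),
                   parameters = list(traits = traits, trials = trials,
                                     k = k, seed = seed, knn_k = knn_k,
                                     impute = impute))
  invisible(results)
}

#' Predict GEBVs of selection candidates with trained models
#'
#' Applies every trait model found in `model_dir` (a [run_train()] output
#' directory) to a candidate genotype file. Candidates are restricted to the
#' markers of each trained model; a shared fraction below `min_overlap`
#' aborts the prediction for safety. When `weights` are given, a selection
#' index over the predicted traits is also written.
#'
#' @param model_dir directory produced by [run_train()].
#' @param genotype_file candidate genotype TSV.
#' @param out_dir output directory.
#' @param list_file optional list file restricting candidates.
#' @param weights optional named numeric vector of trait weights for the
#'   selection index.
#' @param standardize z-score GEBVs per trait before applying index weights.
#' @param knn_k neighbours for KNN imputation of candidate genotypes.
#' @param min_overlap minimum fraction of model markers the candidates must
#'   share (default 0.5).
#' @return (invisibly) named list of candidate GEBV vectors per trait.
#' @export
run_predict <- function(model_dir, genotype_file, out_dir, list_file = NULL,
                        weights = NULL, standardize = FALSE, knn_k = 5L,
                        min_overlap = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eff_files <- list.files(model_dir, pattern = "_marker_effects\\.tsv$",
                          full.names = TRUE)
  if (length(eff_files) == 0L)
    stop("no trained models (\"*_marker_effects.tsv\") found in ", model_dir)
  traits <- sub("_marker_effects\\.tsv$", "", basename(eff_files))

  cand <- read_genotype_matrix(genotype_file)
  if (!is.null(list_file)) {
    keep <- read_individual_list(list_file)
    keep <- intersect(individuals(cand), keep)
    if (length(keep) == 0L)
      stop("no listed individual is present in the candidate genotype file")
    cand <- subset_genotypes(cand, individuals = keep)
  }
  if (anyNA(cand$dosage)) cand <- knn_impute(cand, knn_k)

  predictions <- list()
  for (i in seq_along(traits)) {
    tab <- utils::read.delim(eff_files[i], stringsAsFactors = FALSE)
    eff <- structure(list(
      effects = stats::setNames(tab$effect, tab$marker),
      centering_frequencies = stats::setNames(tab$centering_frequency,
                                              tab$marker),
      scale_constant = NA_real_), class = "marker_effects")
    overlap <- mean(names(eff$effects) %in% markers(cand))
    if (overlap == 0)
      stop("incompatible populations: candidates share no markers with the '",
           traits[i], "' model")
    if (overlap < min_overlap)
      stop(sprintf("marker overlap %.3f below the required minimum %.3f for trait '%s'",
                   overlap, min_overlap, traits[i]))
    pred <- predict_candidates(NULL, eff, cand)
    write_ranking(pred, file.path(out_dir,
                                  paste0(traits[i], "_candidate_gebvs.tsv")),
                  value_name = "gebv")
    predictions[[traits[i]]] <- pred
  }

  if (!is.null(weights)) {
    si <- selection_index(predictions, weights, standardize = standardize)
    write_ranking(si$index, file.path(out_dir, "selection_index.tsv"),
                  value_name = "index")
  }

  write_provenance(out_dir, command = "predict",
                   inputs = list(model_dir = model_dir,
                                 genotype_file = genotype_file,
                                 list_file = list_file),
                   parameters = list(weights = as.list(weights),
                                     standardize = standardize,
                                     knn_k = knn_k,
                                     min_overlap = min_overlap))
  invisible(predictions)
}

# Machine-readable run record: inputs, parameters, package version. No
# wall-clock fields, so identical runs produce identical files.
write_provenance <- function(out_dir, command, inputs, parameters) {
  jsonlite::write_json(
    list(tool = "gselect",
         version = as.character(utils::packageVersion("gselect")),
         command = command, inputs = inputs, parameters = parameters),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
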