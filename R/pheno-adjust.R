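#' Adjusted phenotypes: one value per genotype per trait
#'
#' The response modelled by GBLUP is a single preprocessed phenotype value
#' per genotype. For designed trials the value is the genotype's estimated
#' mean adjusted for replication/block structure; otherwise it is an
#' arithmetic mean of the genotype's plots; across trials it is the mean of
#' the per-trial values.
#'
#' @param trait trait name.
#' @param values named numeric vector, one finite value per genotype.
#' @param method how the values were obtained: `"REML_FIXED_EFFECT"`,
#'   `"ARITHMETIC_MEAN"` or `"CROSS_TRIAL_AVERAGE"`.
#' @param source_trials trial ids the values derive from.
#' @return an object of class `adjusted_phenotypes`.
#' @export
adjusted_phenotypes <- function(trait, values, method, source_trials) {
  method <- match.arg(method, c("REML_FIXED_EFFECT", "ARITHMETIC_MEAN",
                                "CROSS_TRIAL_AVERAGE"))
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("'values' must be named by genotype, without duplicates")
  if (any(!is.finite(values)))
    stop("adjusted phenotype values must be finite")
  structure(list(trait = trait, values = values, method = method,
                 source_trials = source_trials),
            class = "adjusted_phenotypes")
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat(sprintf("adjusted_phenotypes: trait '%s', %d genotypes, method %s\n",
              x$trait, length(x$values), x$method))
  cat("  trials:", paste(x$source_trials, collapse = ", "), "\n")
  invisible(x)
}

# Accept either an adjusted_phenotypes object or a plain named numeric vector.
pheno_values <- function(y) {
  if (inherits(y, "adjusted_phenotypes")) return(y$values)
  if (is.numeric(y) && !is.null(names(y))) return(y)
  stop("'y' must be an adjusted_phenotypes object or a named numeric vector")
}

# A design column is informative only if it is fully recorded for the rows
# being modelled and distinguishes at least two groups.
usable_random_term <- function(v) {
  !any(is.na(v)) && length(unique(v)) >= 2L
}

# Adjusted genotype means from a fixed-effects fit: genotype coefficient plus
# the equal-weight average of the design-factor effects. This is the limit of
# the mixed-model estimates as the residual variance goes to zero (random
# effects unshrunken), used when the data saturate the design exactly and the
# REML fit is degenerate.
ols_adjusted_means <- function(dat, use_rep, use_block) {
  terms <- "0 + genotype"
  if (use_rep) terms <- c(terms, "replication")
  if (use_block) {
    dat$blk <- if (use_rep) interaction(dat$replication, dat$block, drop = TRUE)
               else dat$block
    if (nlevels(factor(dat$blk)) >= 2L) terms <- c(terms, "blk")
  }
  fit <- stats::lm(stats::reformulate(terms, response = "y"), data = dat)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  is_g <- startsWith(names(cf), "genotype")
  est <- cf[is_g]
  names(est) <- sub("^genotype", "", names(est))
  for (fac in c("replication", "blk")) {
    if (any(startsWith(names(cf), fac))) {
      lev <- nlevels(factor(dat[[fac]]))
      est <- est + sum(cf[startsWith(names(cf), fac)]) / lev
    }
  }
  list(means = est, resid_var = mean(stats::resid(fit)^2))
}

#' Adjust plot-level phenotypes within one trial
#'
#' For trials laid out as RCBD, alpha lattice or augmented designs, genotype
#' means are estimated from a linear mixed model fit by REML with genotype as
#' a fixed effect and replication and/or block as random intercepts (block
#' nested within replication when both are recorded). For trials without
#' design information the per-genotype arithmetic mean is used. Plots with a
#' missing trait value are dropped; genotypes left without observations are
#' omitted.
#'
#' @param p a [phenotype_table].
#' @param trait trait column to adjust.
#' @param trial trial id to restrict to.
#' @return an [adjusted_phenotypes] with method `"REML_FIXED_EFFECT"` or
#'   `"ARITHMETIC_MEAN"`.
#' @export
adjust_single_trial <- function(p, trait, trial) {
  if (!trait %in% trait_names(p))
    stop("trait '", trait, "' not found; available: ",
         paste(trait_names(p), collapse = ", "))
  rows <- p[p$trial == trial, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("trial '", trial, "' not found; available: ",
         paste(unique(p$trial), collapse = ", "))
  rows <- rows[!is.na(rows[[trait]]), , drop = FALSE]
  if (length(unique(rows$genotype)) < 2L)
    stop("insufficient data: fewer than 2 genotypes with observations for trait '",
         trait, "' in trial '", trial, "'")

  design <- rows$design[1L]
  use_rep <- usable_random_term(rows$replication)
  use_block <- usable_random_term(rows$block)

  if (design %in% c("RCBD", "ALPHA_LATTICE", "AUGMENTED") && (use_rep || use_block)) {
    dat <- data.frame(y = rows[[trait]],
                      genotype = factor(rows$genotype),
                      replication = factor(rows$replication),
                      block = factor(rows$block))
    # Data that exactly saturate the genotype + design structure leave a zero
    # residual variance, where REML is degenerate; use the limiting
    # fixed-effects adjusted means instead.
    ols <- ols_adjusted_means(dat, use_rep, use_block)
    if (ols$resid_var <= 1e-12 * max(stats::var(dat$y), 1e-300))
      return(adjusted_phenotypes(trait, ols$means, "REML_FIXED_EFFECT", trial))

    random <- if (use_rep && use_block) ~ 1 | replication / block
              else if (use_rep) ~ 1 | replication
              else ~ 1 | block
    fit <- tryCatch(
      nlme::lme(fixed = y ~ 0 + genotype, random = random, data = dat,
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE,
                                           opt = "optim")),
      error = function(e)
        stop("REML adjustment failed to converge for trait '", trait,
             "' in trial '", trial, "': ", conditionMessage(e),
             call. = FALSE))
    est <- nlme::fixef(fit)
    names(est) <- sub("^genotype", "", names(est))
    adjusted_phenotypes(trait, est, "REML_FIXED_EFFECT", trial)
  } else {
    means <- tapply(rows[[trait]], rows$genotype, mean)
    means <- stats::setNames(as.numeric(means), names(means))
    adjusted_phenotypes(trait, means[!is.na(means)], "ARITHMETIC_MEAN", trial)
  }
}

#' Average adjusted phenotypes across trials
#'
#' Genotype effects (or arithmetic means) computed within each trial are
#' averaged, unweighted, across the trials in which each genotype appears,
#' yielding a single phenotype value per genotype.
#'
#' @param parts list of [adjusted_phenotypes] for the same trait.
#' @return an [adjusted_phenotypes] with method `"CROSS_TRIAL_AVERAGE"`.
#' @export
combine_trials <- function(parts) {
  if (length(parts) == 0L)
    stop("combine_trials requires at least one per-trial adjustment")
  parts <- unname(parts)
  traits <- unique(vapply(parts, function(x) x$trait, character(1)))
  if (length(traits) > 1L)
    stop("cannot combine adjustments for different traits: ",
         paste(traits, collapse = ", "))
  all_values <- unlist(lapply(parts, function(x) x$values))
  means <- tapply(all_values, names(all_values), mean)
  values <- stats::setNames(as.numeric(means), names(means))
  trials <- unique(unlist(lapply(parts, function(x) x$source_trials)))
  adjusted_phenotypes(traits, values, "CROSS_TRIAL_AVERAGE", trials)
}

#' Traits phenotyped in every table
#'
#' @param tables list of [phenotype_table]s.
#' @return sorted character vector of trait names having at least one
#'   non-missing observation in every table (possibly empty).
#' @export
common_traits <- function(tables) {
  if (length(tables) == 0L)
    stop("common_traits requires at least one phenotype table")
  per_table <- lapply(tables, function(tb) {
    tn <- trait_names(tb)
    tn[vapply(tn, function(tr) any(!is.na(tb[[tr]])), logical(1))]
  })
  sort(Reduce(intersect, per_table))
}

#' Write adjusted phenotypes to TSV
#'
#' @param y an [adjusted_phenotypes].
#' @param path output path; columns genotype, value, method, trials.
#' @export
write_adjusted_phenotypes <- function(y, path) {
  df <- data.frame(genotype = names(y$values), value = unname(y$values),
                   method = y$method,
                   trials = paste(y$source_trials, collapse = ";"))
  df <- df[order(df$genotype), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
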