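#' Simulate unlinked biallelic genotypes
#'
#' Per marker a minor-allele frequency p is drawn uniformly from `maf_range`
#' and dosages are drawn independently per individual as Binomial(2, p) —
#' unlinked loci in Hardy-Weinberg proportions. Output is `ZERO_1_2` encoded
#' and fully determined by `seed`.
#'
#' @param n number of individuals (>= 2).
#' @param m number of markers (>= 1).
#' @param maf_range `c(lo, hi)` with `0 < lo <= hi <= 0.5`.
#' @param seed integer seed.
#' @return a [genotype_matrix].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.1, 0.5), seed = 1L) {
  if (n < 2L || m < 1L) stop("need n >= 2 individuals and m >= 1 markers")
  if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
      maf_range[1L] > maf_range[2L] || maf_range[2L] > 0.5)
    stop("'maf_range' must satisfy 0 < lo <= hi <= 0.5")
  with_seed(seed, {
    p <- stats::runif(m, maf_range[1L], maf_range[2L])
    M <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    dimnames(M) <- list(sprintf("ind_%0*d", nchar(n), seq_len(n)),
                        sprintf("mk_%0*d", nchar(m), seq_len(m)))
    genotype_matrix(M, "ZERO_1_2")
  })
}

#' Simulate an additive QTL architecture and phenotypes
#'
#' `n_qtl` markers are chosen uniformly without replacement to act as QTL,
#' with effects drawn N(0, 1). True breeding values are the dosage-weighted
#' effect sums; phenotypes add Gaussian noise whose variance is calibrated
#' against the realized (not expected) breeding-value variance so that
#' `var(tbv) / (var(tbv) + se2)` equals the requested heritability exactly
#' for the dataset in hand. With `h2 = 0` the breeding values are identically
#' zero and the phenotype is pure N(0, 1) noise.
#'
#' @param g a [genotype_matrix] (any encoding; dosages used on the {0,1,2}
#'   scale).
#' @param n_qtl number of causal markers, `1 <= n_qtl <= m`.
#' @param h2 target narrow-sense heritability in `[0, 1)`.
#' @param seed integer seed.
#' @return object of class `simulated_population`: list with `genotypes`,
#'   `qtl_ids`, `qtl_effects`, `true_breeding_values`, `phenotypes`,
#'   `sigma_e2`, `h2_target`, `seed`.
#' @export
simulate_phenotypes <- function(g, n_qtl, h2, seed = 1L) {
  m <- ncol(g$dosage)
  if (n_qtl < 1L || n_qtl > m) stop("'n_qtl' must lie in [1, m]")
  if (h2 < 0 || h2 >= 1)
    stop("'h2' must lie in [0, 1); h2 = 1 leaves no room for noise")
  M <- dosage_012(g)
  if (anyNA(M)) stop("simulate_phenotypes requires complete genotypes")
  n <- nrow(M)
  with_seed(seed, {
    qtl <- sort(sample.int(m, n_qtl))
    effects <- stats::setNames(stats::rnorm(n_qtl), colnames(M)[qtl])
    tbv <- drop(M[, qtl, drop = FALSE] %*% effects)
    names(tbv) <- rownames(M)
    if (h2 == 0) {
      tbv[] <- 0
      sigma_e2 <- 1
    } else {
      v <- stats::var(tbv)
      if (v == 0)
        stop("breeding values are constant (monomorphic QTL); cannot hit a ",
             "positive heritability")
      sigma_e2 <- v * (1 - h2) / h2
    }
    phenotypes <- tbv + stats::rnorm(n, 0, sqrt(sigma_e2))
    structure(list(genotypes = g, qtl_ids = colnames(M)[qtl],
                   qtl_effects = effects, true_breeding_values = tbv,
                   phenotypes = phenotypes, sigma_e2 = sigma_e2,
                   h2_target = h2, seed = seed),
              class = "simulated_population")
  })
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf("simulated_population: %d individuals, %d markers, %d QTL, target h2 %.2f\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              length(x$qtl_ids), x$h2_target))
  invisible(x)
}

#' Simulate a replicated field trial
#'
#' Lays genotype values out as a designed trial: each genotype appears once
#' per replication; RCBD adds a random intercept per replication,
#' alpha-lattice and augmented designs add one per incomplete block (blocks
#' of `block_size` genotypes nested in replications), and `UNKNOWN` adds
#' none. Plot noise is i.i.d. N(0, plot_sd^2).
#'
#' @param genotype_values named numeric vector of true genotype means.
#' @param design `"RCBD"`, `"ALPHA_LATTICE"`, `"AUGMENTED"` or `"UNKNOWN"`.
#' @param n_reps replications (>= 1).
#' @param block_sd standard deviation of replication/block intercepts.
#' @param plot_sd standard deviation of plot-level noise.
#' @param seed integer seed.
#' @param block_size genotypes per incomplete block (lattice/augmented).
#' @param trial_id trial label; @param trait trait column name.
#' @return a [phenotype_table] with one row per plot.
#' @export
simulate_trial <- function(genotype_values, design = "RCBD", n_reps = 2L,
                           block_sd = 0, plot_sd = 0, seed = 1L,
                           block_size = 10L, trial_id = "sim_trial",
                           trait = "trait") {
  design <- match.arg(design, c("RCBD", "ALPHA_LATTICE", "AUGMENTED", "UNKNOWN"))
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  genos <- names(genotype_values)
  n <- length(genos)
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      ord <- sample.int(n)    # randomise layout within each replication
      data.frame(trial = trial_id, genotype = genos[ord],
                 replication = sprintf("rep%d", r),
                 block = NA_character_, design = design,
                 value = unname(genotype_values[ord]),
                 stringsAsFactors = FALSE)
    }))
    if (design == "RCBD") {
      b <- stats::rnorm(n_reps, 0, block_sd)
      rows$value <- rows$value + b[as.integer(factor(rows$replication))]
    } else if (design %in% c("ALPHA_LATTICE", "AUGMENTED")) {
      rows$block <- sprintf("b%d", ceiling(seq_len(n) / block_size))[
        stats::ave(seq_len(nrow(rows)), rows$replication, FUN = seq_along)]
      key <- interaction(rows$replication, rows$block, drop = TRUE)
      b <- stats::rnorm(nlevels(key), 0, block_sd)
      rows$value <- rows$value + b[as.integer(key)]
    } else {
      rows$replication <- NA_character_
    }
    rows$value <- rows$value + stats::rnorm(nrow(rows), 0, plot_sd)
    names(rows)[names(rows) == "value"] <- trait
    phenotype_table(rows)
  })
}
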