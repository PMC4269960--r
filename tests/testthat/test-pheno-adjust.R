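make_ptable <- function(...) phenotype_table(data.frame(...))

test_that("arithmetic-mean fallback averages non-missing plots and omits empty genotypes", {
  p <- make_ptable(
    trial = "t1",
    genotype = c("A", "A", "B", "B", "C", "C"),
    design = "UNKNOWN",
    yield = c(4, 6, NA, 3, NA, NA))
  adj <- adjust_single_trial(p, "yield", "t1")
  expect_equal(adj$method, "ARITHMETIC_MEAN")
  expect_equal(adj$values[["A"]], 5)
  expect_equal(adj$values[["B"]], 3)
  expect_false("C" %in% names(adj$values))  # all plots missing -> omitted
})

test_that("balanced RCBD REML genotype means equal raw means", {
  gv <- stats::setNames(rnorm(8, 20, 3), paste0("G", 1:8))
  p <- simulate_trial(gv, "RCBD", n_reps = 3, block_sd = 2, plot_sd = 0.5,
                      seed = 11)
  adj <- adjust_single_trial(p, "trait", "sim_trial")
  expect_equal(adj$method, "REML_FIXED_EFFECT")
  raw <- c(tapply(p$trait, p$genotype, mean))
  expect_equal(adj$values[names(raw)], raw, tolerance = 1e-6)
})

test_that("alpha-lattice adjustment uses block-nested model and tracks truth", {
  gv <- stats::setNames(rnorm(20, 50, 5), paste0("G", 1:20))
  p <- simulate_trial(gv, "ALPHA_LATTICE", n_reps = 2, block_sd = 3,
                      plot_sd = 0.5, seed = 12, block_size = 5)
  adj <- adjust_single_trial(p, "trait", "sim_trial")
  expect_equal(adj$method, "REML_FIXED_EFFECT")
  expect_gt(cor(adj$values[names(gv)], gv), 0.9)
})

test_that("adjustment is translation-equivariant on both routes", {
  gv <- stats::setNames(rnorm(10), paste0("G", 1:10))
  p <- simulate_trial(gv, "RCBD", n_reps = 2, block_sd = 1, plot_sd = 0.4,
                      seed = 13)
  shifted <- p
  shifted$trait <- shifted$trait + 7.5
  a1 <- adjust_single_trial(p, "trait", "sim_trial")
  a2 <- adjust_single_trial(shifted, "trait", "sim_trial")
  expect_equal(a2$values, a1$values + 7.5, tolerance = 1e-6)

  u <- make_ptable(trial = "t1", genotype = rep(c("A", "B"), each = 2),
                   design = "UNKNOWN", y = c(1, 2, 3, 5))
  us <- u; us$y <- us$y + 7.5
  expect_equal(adjust_single_trial(us, "y", "t1")$values,
               adjust_single_trial(u, "y", "t1")$values + 7.5)
})

test_that("with zero block variance REML and arithmetic means agree", {
  gv <- stats::setNames(rnorm(10, 5), paste0("G", 1:10))
  p <- simulate_trial(gv, "RCBD", n_reps = 3, block_sd = 0, plot_sd = 0.3,
                      seed = 14)
  adj <- adjust_single_trial(p, "trait", "sim_trial")
  raw <- c(tapply(p$trait, p$genotype, mean))
  expect_equal(adj$values[names(raw)], raw, tolerance = 1e-6)
})

test_that("cross-trial combination averages per-trial values where present", {
  a1 <- adjusted_phenotypes("yield", c(A = 10, B = 2), "ARITHMETIC_MEAN", "t1")
  a2 <- adjusted_phenotypes("yield", c(A = 20, C = 7), "ARITHMETIC_MEAN", "t2")
  a3 <- adjusted_phenotypes("yield", c(B = 4), "REML_FIXED_EFFECT", "t3")
  comb <- combine_trials(list(a1, a2, a3))
  expect_equal(comb$method, "CROSS_TRIAL_AVERAGE")
  expect_equal(comb$values[["A"]], 15)       # mean of two trials
  expect_equal(comb$values[["B"]], 3)
  expect_equal(comb$values[["C"]], 7)        # present in 1 of 3 trials
  expect_setequal(comb$source_trials, c("t1", "t2", "t3"))
  # permutation invariance
  comb2 <- combine_trials(list(a3, a2, a1))
  expect_equal(comb2$values[names(comb$values)], comb$values)
  # single-trial input keeps the values
  expect_equal(combine_trials(list(a1))$values, a1$values)
  expect_error(combine_trials(list()), "at least one")
  expect_error(combine_trials(list(a1, adjusted_phenotypes(
    "height", c(A = 1, B = 2), "ARITHMETIC_MEAN", "t9"))), "different traits")
})

test_that("common_traits intersects traits with data in every table", {
  t1 <- make_ptable(trial = "t1", genotype = c("A", "B"), design = "UNKNOWN",
                    A = c(1, 2), B = c(3, 4))
  t2 <- make_ptable(trial = "t2", genotype = c("A", "B"), design = "UNKNOWN",
                    B = c(1, 2), C = c(3, 4))
  expect_equal(common_traits(list(t1, t2)), "B")
  expect_equal(common_traits(list(t1)), c("A", "B"))
  t3 <- make_ptable(trial = "t3", genotype = c("A", "B"), design = "UNKNOWN",
                    D = c(1, 2))
  expect_equal(common_traits(list(t1, t3)), character(0))
  # a trait column that is entirely NA does not count as phenotyped
  t4 <- make_ptable(trial = "t4", genotype = c("A", "B"), design = "UNKNOWN",
                    A = c(NA_real_, NA_real_), B = c(1, 2))
  expect_equal(common_traits(list(t1, t4)), "B")
})

test_that("degenerate inputs raise the specified errors", {
  p <- make_ptable(trial = "t1", genotype = c("A", "A"), design = "UNKNOWN",
                   y = c(1, 2))
  expect_error(adjust_single_trial(p, "y", "t1"), "insufficient data")
  expect_error(adjust_single_trial(p, "z", "t1"), "trait 'z' not found")
  expect_error(adjust_single_trial(p, "y", "t9"), "trial 't9' not found")
})
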