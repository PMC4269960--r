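train_fixture <- function(n = 40, m = 120, seed = 1) {
  g <- simulate_genotypes(n, m, seed = seed)
  sim <- simulate_phenotypes(g, 15, 0.5, seed = seed + 50)
  K <- kinship_matrix(g)
  fit <- fit_gblup(sim$phenotypes, K)
  list(g = g, y = sim$phenotypes, K = K, fit = fit,
       eff = marker_effects(fit, g, K))
}

test_that("a candidate identical to a training individual gets its GEBV", {
  fx <- train_fixture()
  cand_d <- fx$g$dosage[c(3, 17), , drop = FALSE]
  rownames(cand_d) <- c("copy_of_3", "copy_of_17")
  pred <- predict_candidates(fx$fit, fx$eff,
                             genotype_matrix(cand_d, "ZERO_1_2"))
  expect_lt(abs(pred[["copy_of_3"]] - fx$fit$gebvs[[3]]), 1e-8)
  expect_lt(abs(pred[["copy_of_17"]] - fx$fit$gebvs[[17]]), 1e-8)
})

test_that("a candidate sitting at the centering frequencies scores zero", {
  fx <- train_fixture(seed = 2)
  p <- fx$eff$centering_frequencies
  cand_d <- rbind(center = 2 * p, other = 2 * p)
  cand <- genotype_matrix(cand_d, "CONTINUOUS", base_encoding = "ZERO_1_2")
  pred <- predict_candidates(fx$fit, fx$eff, cand)
  expect_lt(abs(pred[["center"]]), 1e-10)
})

test_that("marker-effects route equals the relationship-matrix route", {
  fx <- train_fixture(seed = 3)
  cand <- simulate_genotypes(15, 120, seed = 77)   # same marker panel
  pred_marker <- predict_candidates(fx$fit, fx$eff, cand)

  # independent dense route: K_cand,train (K + lambda I)^-1 (y - mu)
  mk <- names(fx$eff$effects)
  p <- fx$eff$centering_frequencies
  W_tr <- sweep(fx$g$dosage[, mk], 2, 2 * p, "-")
  W_cd <- sweep(cand$dosage[, mk], 2, 2 * p, "-")
  K_ct <- W_cd %*% t(W_tr) / fx$K$scale_constant
  n <- nrow(W_tr)
  pred_kinship <- drop(K_ct %*% solve(fx$K$K + fx$fit$lambda * diag(n),
                                      fx$y - fx$fit$mu))
  expect_lt(max(abs(pred_marker - pred_kinship)), 1e-8)
})

test_that("candidate predictions ignore row and marker order", {
  fx <- train_fixture(seed = 4)
  cand <- simulate_genotypes(10, 120, seed = 88)
  pred <- predict_candidates(fx$fit, fx$eff, cand)
  shuffled <- genotype_matrix(
    cand$dosage[c(5, 1, 9, 2, 10, 3, 8, 4, 7, 6), sample(120)], "ZERO_1_2")
  pred2 <- predict_candidates(fx$fit, fx$eff, shuffled)
  expect_equal(pred2[names(pred)], pred, tolerance = 1e-12)
})

test_that("partial marker overlap warns; no overlap errors", {
  fx <- train_fixture(seed = 5)
  cand <- simulate_genotypes(8, 120, seed = 99)
  half <- subset_markers <- markers(cand)[1:60]
  cand_half <- genotype_matrix(cand$dosage[, half], "ZERO_1_2")
  expect_warning(predict_candidates(fx$fit, fx$eff, cand_half), "overlap")
  none <- cand$dosage[, 1:10]
  colnames(none) <- paste0("foreign", 1:10)
  expect_error(predict_candidates(fx$fit, fx$eff,
                                  genotype_matrix(none, "ZERO_1_2")),
               "incompatible populations")
})

test_that("selection index computes weighted GEBV sums over shared genotypes", {
  tables <- list(A = c(g1 = 1, g2 = 3, g3 = 0),
                 B = c(g1 = 2, g2 = 0, g3 = 1))
  si <- selection_index(tables, c(A = 2, B = 1))
  expect_equal(si$index[c("g2", "g1", "g3")], c(g2 = 6, g1 = 4, g3 = 1))
  expect_equal(names(si$index), c("g2", "g1", "g3"))  # sorted descending

  # zero weight annihilates a trait
  si0 <- selection_index(tables, c(A = 1, B = 0))
  expect_equal(si0$index[names(tables$A)], tables$A[names(tables$A)])

  # doubling weights doubles the index, ranking unchanged
  si2 <- selection_index(tables, c(A = 4, B = 2))
  expect_equal(si2$index, 2 * si$index)
  expect_identical(names(si2$index), names(si$index))

  # intersection of genotypes only
  si3 <- selection_index(list(A = c(g1 = 1, g2 = 2), B = c(g2 = 5, g9 = 1)),
                         c(A = 1, B = 1))
  expect_equal(names(si3$index), "g2")
})

test_that("selection index validates its inputs", {
  tables <- list(A = c(g1 = 1))
  expect_error(selection_index(tables, c(Z = 1)), "no GEBV table")
  expect_error(selection_index(tables, numeric(0)), "non-empty")
  expect_error(selection_index(list(A = c(g1 = 1), B = c(g2 = 1)),
                               c(A = 1, B = 1)), "no genotype")
})

test_that("standardized index is invariant to per-trait GEBV scale", {
  tables <- list(A = c(g1 = 1, g2 = 3, g3 = 0, g4 = 2),
                 B = c(g1 = 200, g2 = 0, g3 = 100, g4 = 300))
  w <- c(A = 1, B = 1)
  s1 <- selection_index(tables, w, standardize = TRUE)
  tables2 <- tables
  tables2$B <- tables2$B / 100
  s2 <- selection_index(tables2, w, standardize = TRUE)
  ids <- sort(names(s1$index))
  expect_equal(s1$index[ids], s2$index[ids], tolerance = 1e-12)
})
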