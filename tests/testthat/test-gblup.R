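test_that("kinship matches the direct centered cross-product oracle", {
  # 4 individuals x 6 markers, hand-specified dosages
  d <- rbind(i1 = c(0, 1, 2, 0, 1, 1),
             i2 = c(2, 1, 0, 0, 2, 1),
             i3 = c(1, 0, 1, 0, 2, 2),
             i4 = c(1, 2, 1, 0, 0, 0))
  colnames(d) <- paste0("m", 1:6)
  K <- kinship_matrix(genotype_matrix(d, "ZERO_1_2"))

  # independent computation with explicit loops; m4 is monomorphic
  poly <- c(1, 2, 3, 5, 6)
  p <- colMeans(d[, poly]) / 2
  W <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) W[i, j] <- d[i, poly[j]] - 2 * p[j]
  cc <- 2 * sum(p * (1 - p))
  expect_equal(unname(K$K), W %*% t(W) / cc, tolerance = 1e-12)
  expect_equal(K$scale_constant, cc)
  expect_setequal(names(K$centering_frequencies), paste0("m", poly))

  # symmetry and PSD invariants
  expect_lt(max(abs(K$K - t(K$K))), 1e-10)
  ev <- eigen(K$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("identical genotypes give identical kinship rows", {
  d <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 0, 0, 1))
  colnames(d) <- paste0("m", 1:4)
  K <- kinship_matrix(genotype_matrix(d, "ZERO_1_2"))$K
  expect_equal(K["a", ], K["b", ])
  expect_equal(K["a", "a"], K["a", "b"])
  expect_error(kinship_matrix(genotype_matrix(
    cbind(m1 = c(a = 1, b = 1)), "ZERO_1_2")), "monomorphic")
})

test_that("kinship under Hardy-Weinberg concentrates near the identity", {
  g <- simulate_genotypes(500, 2000, seed = 42)
  K <- kinship_matrix(g)$K
  expect_lt(abs(mean(K[upper.tri(K)])), 0.02)
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
})

test_that("restricted log-likelihood matches its one-term closed form", {
  # n = 2: a single eigenvalue/rotated component
  xi <- 0.8; eta <- 1.3; lam <- 2.0
  sg2 <- eta^2 / (xi + lam)
  expect_equal(restricted_log_likelihood(lam, xi, eta),
               -0.5 * (log(2 * pi * sg2) + log(xi + lam) + 1))
  expect_error(restricted_log_likelihood(0, xi, eta), "positive")
  expect_error(restricted_log_likelihood(-1, xi, eta), "positive")
})

test_that("spectral REML attains the dense-grid oracle maximum", {
  g <- simulate_genotypes(25, 80, seed = 2)
  sim <- simulate_phenotypes(g, 10, 0.4, seed = 3)
  K <- kinship_matrix(g)
  fit <- fit_gblup(sim$phenotypes, K)
  oracle <- oracle_reml_grid(K$K, sim$phenotypes)
  # compare on the oracle's own likelihood surface so constants cancel
  expect_gte(oracle_dense_reml(K$K, sim$phenotypes, fit$lambda),
             oracle$max - 1e-6)
})

test_that("restricted likelihood is invariant to phenotype translation", {
  g <- simulate_genotypes(30, 100, seed = 4)
  sim <- simulate_phenotypes(g, 10, 0.5, seed = 5)
  K <- kinship_matrix(g)
  f1 <- fit_gblup(sim$phenotypes, K)
  f2 <- fit_gblup(sim$phenotypes + 100, K)
  expect_equal(f2$reml_loglik, f1$reml_loglik, tolerance = 1e-8)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-6)
  expect_equal(f2$mu, f1$mu + 100, tolerance = 1e-6)
})

test_that("fit invariants hold: h2 formula, decomposition, zero-sum GEBVs", {
  g <- simulate_genotypes(60, 150, seed = 6)
  sim <- simulate_phenotypes(g, 20, 0.5, seed = 7)
  K <- kinship_matrix(g)
  fit <- fit_gblup(sim$phenotypes, K)
  expect_identical(fit$h2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2))
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  y <- sim$phenotypes[fit$individual_ids]
  expect_equal(fit$mu + fit$gebvs + fit$residuals, y, tolerance = 1e-10)
  expect_lt(abs(sum(fit$gebvs)), 1e-6 * length(y) * sd(y))
})

test_that("rescaling phenotypes rescales variances but not h2 or lambda", {
  g <- simulate_genotypes(50, 120, seed = 8)
  sim <- simulate_phenotypes(g, 15, 0.5, seed = 9)
  K <- kinship_matrix(g)
  f1 <- fit_gblup(sim$phenotypes, K)
  f2 <- fit_gblup(sim$phenotypes * 3, K)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
  expect_equal(f2$sigma_g2, 9 * f1$sigma_g2, tolerance = 1e-4)
  expect_equal(f2$sigma_e2, 9 * f1$sigma_e2, tolerance = 1e-4)
  expect_equal(f2$gebvs, 3 * f1$gebvs, tolerance = 1e-6)
})

test_that("marker effects reproduce the GEBVs through W u = g_hat", {
  g <- simulate_genotypes(50, 200, seed = 10)
  sim <- simulate_phenotypes(g, 25, 0.5, seed = 11)
  K <- kinship_matrix(g)
  fit <- fit_gblup(sim$phenotypes, K)
  eff <- marker_effects(fit, g, K)
  mk <- names(eff$effects)
  W <- sweep(g$dosage[, mk], 2, 2 * eff$centering_frequencies, "-")
  expect_lt(max(abs(drop(W %*% eff$effects) - fit$gebvs)), 1e-8)
})

test_that("monomorphic markers get no effect; duplicated markers share one", {
  set.seed(12)
  d <- matrix(sample(0:2, 30 * 10, replace = TRUE), 30, 10,
              dimnames = list(paste0("i", 1:30), paste0("m", 1:10)))
  d[, 4] <- 2           # monomorphic
  d[, 7] <- d[, 3]      # duplicated column
  g <- genotype_matrix(d, "ZERO_1_2")
  y <- stats::setNames(rnorm(30), rownames(d))
  K <- kinship_matrix(g)
  fit <- fit_gblup(y, K)
  eff <- marker_effects(fit, g, K)
  expect_false("m4" %in% names(eff$effects))
  expect_equal(eff$effects[["m7"]], eff$effects[["m3"]], tolerance = 1e-12)
})

test_that("misaligned phenotypes and kinship are rejected", {
  g <- simulate_genotypes(10, 40, seed = 13)
  K <- kinship_matrix(g)
  y <- stats::setNames(rnorm(5), paste0("other", 1:5))
  expect_error(fit_gblup(y, K), "alignment error")
})
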