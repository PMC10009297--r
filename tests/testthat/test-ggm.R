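test_that("saturated partials match closed forms", {
  # trivariate equicorrelation: every partial = r / (1 + r)
  for (r in c(0.2, 0.5, 0.7)) {
    S <- matrix(r, 3, 3); diag(S) <- 1
    P <- saturated_partials(S)
    expect_equal(P[upper.tri(P)], rep(r / (1 + r), 3), tolerance = 1e-10)
    expect_equal(diag(P), rep(0, 3))
  }
  # diagonal input: all partials zero
  expect_equal(max(abs(saturated_partials(diag(4)))), 0)
  # bivariate: the partial equals the correlation
  S2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(saturated_partials(S2)[1, 2], 0.4, tolerance = 1e-12)
})

test_that("edge p-values follow the Fisher z closed form", {
  P <- matrix(0, 27, 27)
  P[1, 2] <- P[2, 1] <- 0.2
  pv <- edge_pvalues(P, n = 500)
  expect_equal(pv[1, 2], 2 * pnorm(-atanh(0.2) * sqrt(472)),
               tolerance = 1e-12)
  expect_lt(pv[1, 2], 0.001)
  expect_equal(pv[1, 3], 1)          # zero partial
  expect_identical(pv, t(pv))
  expect_equal(diag(pv), rep(1, 27))
  expect_error(edge_pvalues(P, n = 28), "too small")
})

test_that("estimate_correlations validates input and is symmetric", {
  X <- with_seed_test(1, matrix(rnorm(200 * 4), ncol = 4))
  X <- cbind(X, X[, 1])
  est <- estimate_correlations(X)
  expect_equal(est$matrix[1, 5], 1)
  expect_identical(est$matrix, t(est$matrix))
  expect_identical(est$n, 200L)

  Xz <- X; Xz[, 2] <- 3
  colnames(Xz) <- paste0("I", 1:5)
  expect_error(estimate_correlations(Xz), "I2")

  big <- with_seed_test(2, matrix(rnorm(20000 * 4), ncol = 4))
  R <- estimate_correlations(big)$matrix
  expect_lt(max(abs(R[upper.tri(R)])), 0.03)
})

test_that("polychoric correlation recovers the latent correlation", {
  rho <- 0.5
  K <- solve(matrix(c(1, rho, rho, 1), 2))
  dimnames(K) <- list(c("a", "b"), c("a", "b"))
  X <- sample_ordinal_group(K, 1500, seed = 31)
  est <- estimate_correlations(X, method = "polychoric")
  expect_equal(est$matrix[1, 2], rho, tolerance = 0.06)
  # and pearson on the ordinal scores is attenuated toward zero
  expect_lt(estimate_correlations(X)$matrix[1, 2], est$matrix[1, 2])
})

test_that("constrained fit reproduces boundary cases exactly", {
  S <- random_pd_corr(4, seed = 3)
  # saturated: implied covariance equals S
  sat <- fit_constrained_ggm(S, matrix(numeric(0), 0, 2), n = 100)
  expect_equal(sat$sigma, S, tolerance = 1e-10)
  # independence: implied covariance is the diagonal of S
  allp <- which(upper.tri(S), arr.ind = TRUE)
  ind <- fit_constrained_ggm(S, allp, n = 100)
  expect_equal(ind$sigma, diag(diag(S)), tolerance = 1e-8)
})

test_that("single-edge constraint matches a brute-force likelihood optimizer", {
  S <- random_pd_corr(3, seed = 8)
  fit <- fit_constrained_ggm(S, cbind(1L, 3L), n = 50)
  expect_lt(abs(fit$precision[1, 3]), 1e-10)
  # S reproduced on all unconstrained pairs and the diagonal
  expect_equal(fit$sigma[1, 2], S[1, 2], tolerance = 1e-7)
  expect_equal(fit$sigma[2, 3], S[2, 3], tolerance = 1e-7)
  expect_equal(diag(fit$sigma), diag(S), tolerance = 1e-7)
  oracle <- brute_force_ggm(S, cbind(1L, 3L))
  expect_equal(fit$sigma, oracle, tolerance = 1e-5)
})

test_that("fit indices recover hand-computed discrepancies", {
  S <- random_pd_corr(5, seed = 4)
  sat <- fit_constrained_ggm(S, matrix(numeric(0), 0, 2), n = 200)
  fi <- fit_indices(sat$logL, S, sat$sigma, n = 200, df = 0)
  expect_equal(fi$chi_square, 0, tolerance = 1e-7)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$tli, 1)

  # bivariate with the single edge pruned: F = -ln(1 - r^2)
  r <- 0.5
  S2 <- matrix(c(1, r, r, 1), 2)
  pr <- fit_constrained_ggm(S2, cbind(1L, 2L), n = 150)
  fi2 <- fit_indices(pr$logL, S2, pr$sigma, n = 150, df = 1)
  expect_equal(fi2$chi_square, (150 - 1) * -log(1 - r^2), tolerance = 1e-10)

  # independence model fit to independent data: T/df near 1 at large n
  X <- with_seed_test(5, matrix(rnorm(5000 * 6), ncol = 6))
  S3 <- cor(X)
  allp <- which(upper.tri(S3), arr.ind = TRUE)
  ind <- fit_constrained_ggm(S3, allp, n = 5000)
  fi3 <- fit_indices(ind$logL, S3, ind$sigma, n = 5000, df = nrow(allp))
  expect_lt(abs(fi3$chi_square / fi3$df - 1), 0.75)
})

test_that("pruning recovers a planted sparse network at n = 2000", {
  spec <- true_network_spec(seed = 42, weight_range = c(0.15, 0.35))
  K <- build_true_precision(spec)
  X <- sample_ordinal_group(K, 2000, seed = 7)
  net <- prune_network(estimate_correlations(X),
                       communities = spec_communities(spec))
  truthP <- precision_to_partials(K)
  ut <- upper.tri(truthP)
  true_edges <- abs(truthP[ut]) > 1e-9
  est_edges <- net$weights[ut] != 0
  expect_gte(mean(est_edges[true_edges]), 0.9)
  expect_lte(mean(est_edges[!true_edges]), 0.1)
  # weights are zero exactly on the zero pattern, diagonal zero
  expect_true(all((net$weights == 0)[net$zero_pattern]))
  expect_equal(diag(net$weights), setNames(rep(0, 27), colnames(net$weights)))
  # implied covariance reproduces S on retained pairs
  S <- cor(X)
  retained <- !net$zero_pattern & upper.tri(S)
  expect_lt(max(abs(net$sigma[retained] - S[retained])), 1e-7)
})

test_that("alpha = 1 prunes nothing and order does not matter", {
  ds <- make_two_group_data(n = 250, seed = 3)
  est <- estimate_correlations(ds$a)
  sat <- prune_network(est, alpha = 1)
  expect_identical(sat$fit$df, 0L)
  expect_equal(sat$weights, saturated_partials(est), tolerance = 1e-10)

  net <- prune_network(est, alpha = 0.05)
  perm <- sample(ncol(ds$a))
  net_p <- prune_network(estimate_correlations(ds$a[, perm]), alpha = 0.05)
  expect_equal(net_p$weights[colnames(ds$a), colnames(ds$a)], net$weights,
               tolerance = 1e-8)

  # monotonicity of the first pruning round in alpha
  pv <- edge_pvalues(saturated_partials(est), est$n)
  for (a2 in c(0.01, 0.05, 0.2)) {
    kept_small <- pv < a2
    kept_large <- pv < 0.5
    expect_true(all(kept_large[kept_small]))
  }
})

test_that("type-I edge retention under the empty graph stays near alpha", {
  p <- 10
  K <- diag(p); dimnames(K) <- list(paste0("V", 1:p), paste0("V", 1:p))
  kept <- with_seed_test(99, {
    vapply(1:60, function(i) {
      X <- matrix(rnorm(1000 * p), ncol = p)
      net <- prune_network(cor(X), n = 1000, alpha = 0.05)
      mean(net$weights[upper.tri(net$weights)] != 0)
    }, numeric(1))
  })
  expect_lt(abs(mean(kept) - 0.05), 0.03)
})
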