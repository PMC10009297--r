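test_that("zero case-drop reproduces the full-sample network every time", {
  ds <- make_two_group_data(n = 300, seed = 31)
  boot <- casedrop_bootstrap(ds$a, n_boot = 5, drop_fraction = 0, seed = 1)
  full_edges <- boot$full_network$weights[upper.tri(diag(27))] != 0
  expect_true(all(boot$edge_inclusion$inclusion %in% c(0, 1)))
  expect_equal(boot$edge_inclusion$inclusion, as.numeric(full_edges))
  expect_equal(boot$overall_recovery, 1)
})

test_that("bootstrap aggregates are consistent bookkeeping", {
  ds <- make_two_group_data(n = 400, seed = 32)
  boot <- casedrop_bootstrap(ds$a, n_boot = 30, drop_fraction = 0.25,
                             seed = 2)
  inc <- boot$edge_inclusion$inclusion
  expect_true(all(inc >= 0 & inc <= 1))
  present <- boot$edge_inclusion$full_weight != 0
  expect_equal(boot$overall_recovery, mean(inc[present]))
  # determinism under a fixed seed
  boot2 <- casedrop_bootstrap(ds$a, n_boot = 30, drop_fraction = 0.25,
                              seed = 2)
  expect_equal(boot$edge_inclusion, boot2$edge_inclusion)
  expect_error(casedrop_bootstrap(ds$a[1:40, ], drop_fraction = 0.5),
               "too small")
})

test_that("variability network is the per-edge sample SD across groups", {
  nm <- paste0("V", 1:3)
  w1 <- matrix(0, 3, 3, dimnames = list(nm, nm))
  w2 <- w1
  w1[1, 2] <- w1[2, 1] <- 0.2
  w2[1, 2] <- w2[2, 1] <- 0.4
  v <- variability_network(list(g1 = w1, g2 = w2))
  expect_equal(v$edge_sd[1, 2], sd(c(0.2, 0.4)))
  expect_equal(v$edge_sd[1, 2], 0.1414, tolerance = 1e-3)
  expect_equal(v$edge_sd[1, 3], 0)  # absent in both -> zero SD
  # identical networks: all zero
  v0 <- variability_network(list(w1, w1))
  expect_equal(max(v0$edge_sd), 0)
  expect_equal(max(abs(v0$node_ei_sd)), 0)
  # invariant to group order
  vr <- variability_network(list(g2 = w2, g1 = w1))
  expect_equal(vr$edge_sd, v$edge_sd)
  # node EI SD
  expect_equal(unname(v$node_ei_sd[1]), sd(c(0.2, 0.4)))
  expect_error(variability_network(list(w1)), "at least 2")
  expect_error(variability_network(list(w1, w2[1:2, 1:2])), "node set")
})

test_that("top_varying_edges ranks deterministically and takes a ceiling", {
  nm <- paste0("V", 1:6)
  k <- length(nm)
  sdm <- matrix(0, k, k, dimnames = list(nm, nm))
  vals <- c(0.5, 0.4, 0.3, 0.25, 0.2, 0.15, 0.1, 0.05)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4),
                 c(5, 6), c(4, 5))
  for (t in seq_len(nrow(pairs))) {
    sdm[pairs[t, 1], pairs[t, 2]] <- sdm[pairs[t, 2], pairs[t, 1]] <- vals[t]
  }
  v <- list(edge_sd = sdm, node_ei_sd = setNames(rep(0, k), nm))
  class(v) <- "variability_network"
  top <- top_varying_edges(v, fraction = 0.25)
  expect_identical(nrow(top), 2L)  # ceiling(0.25 * 8)
  expect_identical(top$item_i[1], "V1")
  expect_identical(top$item_j[1], "V2")
  expect_identical(nrow(top_varying_edges(v, fraction = 1)), 8L)

  # a planted high-variability edge (present in one group only) ranks first
  w1 <- matrix(0, k, k, dimnames = list(nm, nm))
  w2 <- w1; w3 <- w1
  w1[1, 2] <- w1[2, 1] <- 0.4
  w2[3, 4] <- w2[4, 3] <- 0.1; w3[3, 4] <- w3[4, 3] <- 0.12
  vv <- variability_network(list(w1, w2, w3))
  t1 <- top_varying_edges(vv, fraction = 1)
  expect_identical(c(t1$item_i[1], t1$item_j[1]), c("V1", "V2"))
})

test_that("strong edges stay included under 25% case-drop", {
  spec <- true_network_spec(seed = 51, weight_range = c(0.25, 0.35),
                            within_density = 0.12, bridge_count = 6,
                            negative_bridge_count = 1)
  K <- build_true_precision(spec)
  X <- sample_ordinal_group(K, 2000, seed = 52)
  boot <- casedrop_bootstrap(X, n_boot = 40, drop_fraction = 0.25, seed = 53)
  P <- precision_to_partials(K)
  truth <- P[upper.tri(P)]
  strong <- abs(truth) >= 0.25
  expect_true(all(boot$edge_inclusion$inclusion[strong] >= 0.9))
  absent <- abs(truth) < 1e-9
  expect_lte(mean(boot$edge_inclusion$inclusion[absent]), 0.09)
})
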