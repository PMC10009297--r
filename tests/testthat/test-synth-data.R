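test_that("empty and structured precision matrices honor requested support", {
  empty <- true_network_spec(within_density = 0, bridge_count = 0,
                             negative_bridge_count = 0, seed = 3)
  K <- build_true_precision(empty)
  expect_equal(max(abs(K[upper.tri(K)])), 0)

  spec <- true_network_spec(within_density = 0.1, bridge_count = 4,
                            negative_bridge_count = 1, seed = 9)
  K <- build_true_precision(spec)
  P <- precision_to_partials(K)
  comm <- spec_communities(spec)
  cross <- outer(comm, comm, "!=")
  bridges <- P[upper.tri(P) & cross]
  expect_identical(sum(bridges != 0), 4L)
  expect_identical(sum(bridges < 0), 1L)
  within <- P[upper.tri(P) & !cross]
  n_within <- round(0.1 * (choose(10, 2) + choose(17, 2)))
  expect_identical(sum(within != 0), as.integer(n_within))
  expect_true(all(within >= 0))
})

test_that("generated precision matrices are PD with unit-variance latents", {
  for (s in c(1, 7, 123)) {
    spec <- true_network_spec(seed = s, weight_range = c(0.15, 0.35))
    K <- build_true_precision(spec)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lt(max(abs(diag(solve(K)) - 1)), 1e-10)
  }
})

test_that("infeasible edge requests are rejected up front", {
  expect_error(true_network_spec(bridge_count = 1000),
               "between-community pairs")
  expect_error(true_network_spec(bridge_count = 2, negative_bridge_count = 3),
               "negative_bridge_count")
})

test_that("ordinal sampling reproduces the latent model's margins and independence", {
  p <- 6
  K <- diag(p)
  dimnames(K) <- list(paste0("V", 1:p), paste0("V", 1:p))
  X <- sample_ordinal_group(K, 20000, thresholds = qnorm(c(0.2, 0.4, 0.6, 0.8)),
                            seed = 21)
  R <- cor(X)
  expect_lt(max(abs(R[upper.tri(R)])), 0.03)
  freqs <- table(X[, 1]) / nrow(X)
  expect_true(all(abs(freqs - 0.2) < 0.02))

  one <- sample_ordinal_group(K, 1, seed = 2)
  expect_identical(nrow(one), 1L)
  expect_true(all(one %in% 1:5))
})

test_that("ordinal sampling refuses a non-PD precision", {
  K <- diag(2); K[1, 2] <- K[2, 1] <- -1.5
  expect_error(sample_ordinal_group(K, 10), "positive definite")
})

test_that("generate_study assembles groups with exact straight-liner counts", {
  spec <- true_network_spec(seed = 4)
  gs <- list(group_spec("north", spec, 100),
             group_spec("south", spec, 100))
  ds <- generate_study(gs, seed = 8)
  expect_identical(nrow(ds$responses), 200L)
  constant <- apply(ds$responses, 1, function(r) all(r == r[1]))
  expect_identical(sum(constant), 0L)

  gs2 <- list(group_spec("g", spec, 500, straightliner_rate = 0.1))
  ds2 <- generate_study(gs2, seed = 8)
  constant2 <- apply(ds2$responses, 1, function(r) all(r == r[1]))
  expect_identical(sum(constant2), 50L)

  ds2b <- generate_study(gs2, seed = 8)
  expect_identical(ds2, ds2b)
})

test_that("survey CSV round-trips responses, groups and demographics", {
  spec <- true_network_spec(seed = 4)
  ds <- generate_study(list(group_spec("x", spec, 40)), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(ds, path)
  back <- read_survey_csv(path)
  expect_identical(unname(back$responses), unname(ds$responses))
  expect_identical(back$group, ds$group)
  expect_identical(back$age, ds$age)
  expect_identical(back$community, ds$community)

  truth_path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(ds, truth_path)
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  K <- attr(ds, "truth")$x$precision
  expect_equal(truth$x$precision, matrix(as.numeric(K), nrow(K)),
               tolerance = 1e-12)
})

test_that("perturb_precision plants exactly the requested differing edges", {
  spec <- true_network_spec(seed = 6, weight_range = c(0.15, 0.35),
                            within_density = 0.10, bridge_count = 6)
  K <- build_true_precision(spec)
  K2 <- perturb_precision(K, n_edges = 10, delta = 0.2, seed = 13)
  expect_false(attr(K2, "repaired"))
  P1 <- precision_to_partials(K)
  P2 <- precision_to_partials(K2)
  diff <- abs(P1 - P2) > 1e-9
  expect_identical(sum(diff[upper.tri(diff)]), 10L)
  planted <- attr(K2, "perturbed_pairs")
  expect_true(all(abs(P2[planted] - 0.2) < 1e-9))
})
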