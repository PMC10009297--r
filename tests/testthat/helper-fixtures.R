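# Shared fixtures and independent oracles used across the test files.

# Random positive-definite correlation matrix (via a random Gram matrix).
random_pd_corr <- function(p, seed) {
  with_seed_test(seed, {
    A <- matrix(rnorm(p * (p + 3)), p + 3, p)
    stats::cov2cor(crossprod(A) / (p + 3))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force covariance selection oracle: directly maximizes the Gaussian
# likelihood over the free entries of the precision matrix under the zero
# constraints, with a quasi-Newton optimizer.  Independent of the package's
# sweep-based fit.
brute_force_ggm <- function(S, zero_pairs) {
  p <- ncol(S)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  constrained <- rep(FALSE, nrow(pairs))
  if (length(zero_pairs)) {
    zp <- matrix(zero_pairs, ncol = 2)
    for (t in seq_len(nrow(zp))) {
      constrained <- constrained |
        (pairs[, 1] == zp[t, 1] & pairs[, 2] == zp[t, 2]) |
        (pairs[, 1] == zp[t, 2] & pairs[, 2] == zp[t, 1])
    }
  }
  free <- pairs[!constrained, , drop = FALSE]
  build_K <- function(par) {
    K <- diag(exp(par[seq_len(p)]), p)
    if (nrow(free)) {
      for (t in seq_len(nrow(free))) {
        K[free[t, 1], free[t, 2]] <- K[free[t, 2], free[t, 1]] <-
          par[p + t]
      }
    }
    K
  }
  # negative profile log-likelihood (up to constants): -log|K| + tr(SK)
  nll <- function(par) {
    K <- build_K(par)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) return(1e10)
    -sum(log(ev)) + sum(S * K)
  }
  init <- c(rep(0, p), rep(0, nrow(free)))
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  solve(build_K(opt$par))
}

# Small two-group ordinal fixture used by several comparison tests.
make_two_group_data <- function(n = 300, seed = 11,
                                spec = true_network_spec(
                                  seed = 5, weight_range = c(0.15, 0.35))) {
  K <- build_true_precision(spec)
  list(K = K, comm = spec_communities(spec),
       a = sample_ordinal_group(K, n, seed = seed),
       b = sample_ordinal_group(K, n, seed = seed + 1))
}
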