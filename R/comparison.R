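#' Symmetric Kullback-Leibler divergence of two zero-mean Gaussians
#'
#' `KL(a -> b) + KL(b -> a) = 0.5 * (tr(Sb^-1 Sa) + tr(Sa^-1 Sb)) - p`.
#'
#' @param sigma_a,sigma_b positive-definite covariance matrices of equal
#'   dimension.
#' @return non-negative divergence value.
#' @export
symmetric_kl <- function(sigma_a, sigma_b) {
  if (!identical(dim(sigma_a), dim(sigma_b))) {
    stop("covariance matrices must have the same dimension", call. = FALSE)
  }
  stop_if_not_pd(sigma_a, "sigma_a")
  stop_if_not_pd(sigma_b, "sigma_b")
  p <- ncol(sigma_a)
  0.5 * (sum(diag(solve(sigma_b, sigma_a))) +
           sum(diag(solve(sigma_a, sigma_b)))) - p
}

# Minimal estimation path used inside resampling loops: Pearson correlations
# then recursive pruning, returning the C++ result directly.
prune_raw <- function(X, alpha = 0.05, tol = 1e-8, max_sweeps = 1000) {
  S <- cor(X)
  .cpp_prune(S, nrow(X), alpha, tol, as.integer(max_sweeps))
}

# Per-network statistics used by the permutation tests.  `cross` is the
# between-community indicator matrix, `other_size` the size of the opposite
# community per node.
net_stats <- function(w, cross, other_size) {
  ei <- colSums(w)
  braw <- colSums(w * cross)
  bnorm <- braw / other_size
  list(ei = ei, bnorm = bnorm, g_ei = sum(ei), g_bei = sum(bnorm))
}

community_helpers <- function(community, items) {
  comm <- community[items]
  cross <- outer(comm, comm, "!=")
  sizes <- table(comm)
  other_size <- vapply(comm, function(cm) sum(sizes[names(sizes) != cm]),
                       numeric(1))
  list(comm = comm, cross = cross, other_size = other_size)
}

#' Posterior-predictive test of overall network structure difference
#'
#' Tests whether two groups' networks differ at an overall structural level.
#' The observed statistic is the symmetric KL divergence between the two
#' groups' pruned-model-implied covariances.  Its null distribution is
#' generated from a plug-in predictive: the pooled data are fit with the
#' same pruning pipeline, and each of `n_draws` replicates simulates two
#' Gaussian datasets of the original group sizes from the pooled fit,
#' re-estimates each implied covariance through the pipeline, and records
#' their symmetric KL.  `p = (1 + #\{null >= observed\}) / (1 + n_draws)`.
#'
#' @param data_a,data_b respondent-by-item matrices (or `survey_dataset`s)
#'   over the same items.
#' @param n_draws number of predictive draws (default 1000).
#' @param alpha pruning significance level used throughout.
#' @param seed integer seed.
#' @return list with `kl_observed`, `kl_p`, `null_distribution`, `n_draws`.
#' @export
ppc_structure_test <- function(data_a, data_b, n_draws = 1000, alpha = 0.05,
                               seed = 1) {
  if (inherits(data_a, "survey_dataset")) data_a <- data_a$responses
  if (inherits(data_b, "survey_dataset")) data_b <- data_b$responses
  if (n_draws < 1) stop("n_draws must be at least 1", call. = FALSE)
  if (!identical(colnames(data_a), colnames(data_b)) ||
      ncol(data_a) != ncol(data_b)) {
    stop("both groups must share the same items", call. = FALSE)
  }
  na <- nrow(data_a); nb <- nrow(data_b)
  fit_a <- prune_raw(data_a, alpha)
  fit_b <- prune_raw(data_b, alpha)
  kl_obs <- symmetric_kl(fit_a$sigma, fit_b$sigma)

  pooled <- rbind(data_a, data_b)
  fit_pool <- prune_raw(pooled, alpha)
  R <- chol(fit_pool$sigma)

  null_kl <- rep(NA_real_, n_draws)
  with_seed(seed, {
    for (d in seq_len(n_draws)) {
      null_kl[d] <- tryCatch({
        za <- rmvnorm_chol(na, R)
        zb <- rmvnorm_chol(nb, R)
        symmetric_kl(prune_raw(za, alpha)$sigma, prune_raw(zb, alpha)$sigma)
      }, error = function(e) NA_real_)
    }
  })
  ok <- !is.na(null_kl)
  if (mean(!ok) > 0.01) {
    stop(sprintf("%.1f%% of predictive draws failed", 100 * mean(!ok)),
         call. = FALSE)
  }
  used <- null_kl[ok]
  list(kl_observed = kl_obs,
       kl_p = (1 + sum(used >= kl_obs)) / (1 + length(used)),
       null_distribution = used, n_draws = n_draws)
}

# Shared permutation engine: one permutation stream supplies the global
# expected-influence tests and the edge/node-level tests for a pair of
# groups.
nct_engine <- function(data_a, data_b, community, n_permutations = 5000,
                       alpha = 0.05, sig_level = 0.05, seed = 1) {
  if (inherits(data_a, "survey_dataset")) data_a <- data_a$responses
  if (inherits(data_b, "survey_dataset")) data_b <- data_b$responses
  if (!identical(colnames(data_a), colnames(data_b))) {
    stop("both groups must share the same items", call. = FALSE)
  }
  items <- colnames(data_a)
  ch <- community_helpers(community, items)
  na <- nrow(data_a); nb <- nrow(data_b)
  p <- ncol(data_a)

  fa <- prune_raw(data_a, alpha)
  fb <- prune_raw(data_b, alpha)
  sa <- net_stats(fa$weights, ch$cross, ch$other_size)
  sb <- net_stats(fb$weights, ch$cross, ch$other_size)

  ut <- upper.tri(fa$weights)
  universe <- which(ut & (fa$weights != 0 | fb$weights != 0))
  pair_idx <- which(ut, arr.ind = TRUE)
  lin <- which(ut)
  uni_rows <- match(universe, lin)
  edge_items <- cbind(items[pair_idx[uni_rows, 1]],
                      items[pair_idx[uni_rows, 2]])
  edge_bridge <- ch$comm[edge_items[, 1]] != ch$comm[edge_items[, 2]]

  obs <- list(g_ei = abs(sa$g_ei - sb$g_ei),
              g_bei = abs(sa$g_bei - sb$g_bei),
              edge = abs(fa$weights[universe] - fb$weights[universe]),
              node_ei = abs(sa$ei - sb$ei),
              node_bei = abs(sa$bnorm - sb$bnorm))

  pooled <- rbind(data_a, data_b)
  ntot <- na + nb
  B <- n_permutations
  null_g_ei <- null_g_bei <- rep(NA_real_, B)
  null_edge <- matrix(NA_real_, B, length(universe))
  null_node_ei <- null_node_bei <- matrix(NA_real_, B, p)

  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(ntot, na)
      res <- tryCatch({
        pa <- prune_raw(pooled[idx, , drop = FALSE], alpha)
        pb <- prune_raw(pooled[-idx, , drop = FALSE], alpha)
        list(pa = pa, pb = pb)
      }, error = function(e) NULL)
      if (is.null(res)) next
      ssa <- net_stats(res$pa$weights, ch$cross, ch$other_size)
      ssb <- net_stats(res$pb$weights, ch$cross, ch$other_size)
      null_g_ei[b] <- abs(ssa$g_ei - ssb$g_ei)
      null_g_bei[b] <- abs(ssa$g_bei - ssb$g_bei)
      null_edge[b, ] <- abs(res$pa$weights[universe] -
                              res$pb$weights[universe])
      null_node_ei[b, ] <- abs(ssa$ei - ssb$ei)
      null_node_bei[b, ] <- abs(ssa$bnorm - ssb$bnorm)
    }
  })

  ok <- !is.na(null_g_ei)
  if (mean(!ok) > 0.01) {
    stop(sprintf("%.1f%% of permutations failed to estimate",
                 100 * mean(!ok)), call. = FALSE)
  }
  Beff <- sum(ok)
  perm_p <- function(null, ob) (1 + sum(null >= ob)) / (1 + Beff)

  per_edge_p <- vapply(seq_along(universe), function(t) {
    perm_p(null_edge[ok, t], obs$edge[t])
  }, numeric(1))
  per_node_ei_p <- vapply(seq_len(p), function(t) {
    perm_p(null_node_ei[ok, t], obs$node_ei[t])
  }, numeric(1))
  per_node_bei_p <- vapply(seq_len(p), function(t) {
    perm_p(null_node_bei[ok, t], obs$node_bei[t])
  }, numeric(1))

  per_edge <- data.frame(item_i = edge_items[, 1], item_j = edge_items[, 2],
                         is_bridge = unname(edge_bridge),
                         weight_a = fa$weights[universe],
                         weight_b = fb$weights[universe],
                         diff = obs$edge, p = per_edge_p,
                         p_holm = stats::p.adjust(per_edge_p, "holm"))
  per_node <- data.frame(item = items, community = unname(ch$comm),
                         ei_a = unname(sa$ei), ei_b = unname(sb$ei),
                         ei_diff = unname(obs$node_ei), ei_p = per_node_ei_p,
                         bei_a = unname(sa$bnorm), bei_b = unname(sb$bnorm),
                         bei_diff = unname(obs$node_bei),
                         bei_p = per_node_bei_p)

  list(global_ei_diff = obs$g_ei,
       global_ei_p = perm_p(null_g_ei[ok], obs$g_ei),
       global_bridge_ei_diff = obs$g_bei,
       global_bridge_ei_p = perm_p(null_g_bei[ok], obs$g_bei),
       per_edge = per_edge, per_node = per_node,
       edge_diff_count = sum(per_edge$p < sig_level),
       bridge_edge_diff_count = sum(per_edge$p < sig_level &
                                      per_edge$is_bridge),
       nonbridge_edge_diff_count = sum(per_edge$p < sig_level &
                                         !per_edge$is_bridge),
       node_ei_diff_count = sum(per_node$ei_p < sig_level),
       node_bridge_ei_diff_count = sum(per_node$bei_p < sig_level),
       n_permutations = n_permutations, n_permutations_used = Beff,
       net_a = fa, net_b = fb, seed = seed)
}

#' Permutation test of a global network statistic
#'
#' Tests the absolute difference in global expected influence (or global
#' bridge expected influence) between two groups.  Group labels are shuffled
#' over the pooled respondents keeping the original group sizes, the entire
#' pruning pipeline is re-run on each permuted split, and the statistic
#' difference is recomputed; `p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations)`.
#'
#' @param data_a,data_b respondent-by-item matrices over the same items.
#' @param community item-to-community map.
#' @param statistic `"global_ei"` or `"global_bridge_ei"`.
#' @param n_permutations number of label permutations (default 5000).
#' @param alpha pruning level used inside the pipeline.
#' @param seed integer seed.
#' @return list with `diff_observed`, `p`, `n_permutations`.
#' @export
nct_global <- function(data_a, data_b, community,
                       statistic = c("global_ei", "global_bridge_ei"),
                       n_permutations = 5000, alpha = 0.05, seed = 1) {
  statistic <- match.arg(statistic)
  eng <- nct_engine(data_a, data_b, community, n_permutations, alpha,
                    seed = seed)
  if (statistic == "global_ei") {
    list(diff_observed = eng$global_ei_diff, p = eng$global_ei_p,
         n_permutations = eng$n_permutations)
  } else {
    list(diff_observed = eng$global_bridge_ei_diff,
         p = eng$global_bridge_ei_p,
         n_permutations = eng$n_permutations)
  }
}

#' Permutation tests of edge- and node-level network differences
#'
#' Element-wise permutation tests over the union of edges retained in either
#' group's pruned network, and over node expected influence and normalized
#' bridge expected influence, sharing one permutation stream with the global
#' tests.  Significance counts (at `sig_level`) are split into bridge and
#' non-bridge edges.
#'
#' @inheritParams nct_global
#' @param sig_level level at which difference counts are taken (default .05,
#'   uncorrected; Holm-adjusted p-values are also returned).
#' @return list with `per_edge`, `per_node` tables and difference counts.
#' @export
nct_local <- function(data_a, data_b, community, n_permutations = 5000,
                      alpha = 0.05, sig_level = 0.05, seed = 1) {
  eng <- nct_engine(data_a, data_b, community, n_permutations, alpha,
                    sig_level, seed)
  eng[c("per_edge", "per_node", "edge_diff_count", "bridge_edge_diff_count",
        "nonbridge_edge_diff_count", "node_ei_diff_count",
        "node_bridge_ei_diff_count", "n_permutations")]
}

#' Full pairwise comparison of two group networks
#'
#' Combines the posterior-predictive structure test with the permutation
#' tests of global and element-wise differences.  The two groups are
#' canonicalized by sorting their labels, so results do not depend on
#' argument order.
#'
#' @param data_a,data_b respondent-by-item matrices (or `survey_dataset`s).
#' @param community item-to-community map.
#' @param label_a,label_b group labels.
#' @param n_permutations label permutations for the NCT tests.
#' @param n_ppc_draws predictive draws for the structure test.
#' @param alpha pruning level.
#' @param sig_level level for difference counts.
#' @param seed integer seed.
#' @return a `pairwise_comparison` object.
#' @export
compare_networks <- function(data_a, data_b, community,
                             label_a = "group_a", label_b = "group_b",
                             n_permutations = 5000, n_ppc_draws = 1000,
                             alpha = 0.05, sig_level = 0.05, seed = 1) {
  if (inherits(data_a, "survey_dataset")) data_a <- data_a$responses
  if (inherits(data_b, "survey_dataset")) data_b <- data_b$responses
  if (label_b < label_a) {  # canonical order
    tmp <- data_a; data_a <- data_b; data_b <- tmp
    tmpl <- label_a; label_a <- label_b; label_b <- tmpl
  }
  ppc <- ppc_structure_test(data_a, data_b, n_ppc_draws, alpha,
                            seed = derive_seed(seed, 1L))
  eng <- nct_engine(data_a, data_b, community, n_permutations, alpha,
                    sig_level, seed = derive_seed(seed, 2L))
  structure(list(group_a = label_a, group_b = label_b,
                 kl_observed = ppc$kl_observed, kl_p = ppc$kl_p,
                 global_ei_diff = eng$global_ei_diff,
                 global_ei_p = eng$global_ei_p,
                 global_bridge_ei_diff = eng$global_bridge_ei_diff,
                 global_bridge_ei_p = eng$global_bridge_ei_p,
                 edge_diff_count = eng$edge_diff_count,
                 bridge_edge_diff_count = eng$bridge_edge_diff_count,
                 nonbridge_edge_diff_count = eng$nonbridge_edge_diff_count,
                 node_ei_diff_count = eng$node_ei_diff_count,
                 node_bridge_ei_diff_count = eng$node_bridge_ei_diff_count,
                 per_edge_p = eng$per_edge, per_node_p = eng$per_node,
                 n_permutations = n_permutations,
                 n_ppc_draws = n_ppc_draws, seed = seed),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("pairwise_comparison: %s vs %s\n", x$group_a, x$group_b))
  cat(sprintf("  structure: KL = %.3f, p = %.4f\n", x$kl_observed, x$kl_p))
  cat(sprintf("  global EI diff = %.3f (p = %.4f); global bridge EI diff = %.4f (p = %.4f)\n",
              x$global_ei_diff, x$global_ei_p, x$global_bridge_ei_diff,
              x$global_bridge_ei_p))
  cat(sprintf("  differing edges: %d (%d bridge, %d non-bridge); nodes: %d EI, %d bridge EI\n",
              x$edge_diff_count, x$bridge_edge_diff_count,
              x$nonbridge_edge_diff_count, x$node_ei_diff_count,
              x$node_bridge_ei_diff_count))
  invisible(x)
}
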