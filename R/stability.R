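#' Case-drop bootstrap stability of a pruned network
#'
#' Each replicate drops `floor(drop_fraction * n)` distinct respondents
#' uniformly at random (without replacement), re-runs the full pruning
#' pipeline on the remainder, and records which edges were retained and
#' their weights.  Aggregates the per-edge inclusion proportion, weight
#' quantiles and the mean inclusion of the edges present in the full-sample
#' network — the headline stability summary.
#'
#' @param data one group's respondent-by-item matrix (or `survey_dataset`).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param drop_fraction fraction of respondents omitted per replicate
#'   (default 0.25).
#' @param alpha pruning level.
#' @param seed integer seed.
#' @return a `bootstrap_result`: list with `edge_inclusion` (matrix),
#'   `weight_quantiles` (per-edge 2.5/50/97.5 percentiles),
#'   `overall_recovery`, `full_network`, `n_boot`, `n_failed`,
#'   `drop_fraction`.
#' @export
casedrop_bootstrap <- function(data, n_boot = 1000, drop_fraction = 0.25,
                               alpha = 0.05, seed = 1) {
  if (inherits(data, "survey_dataset")) data <- data$responses
  n <- nrow(data)
  p <- ncol(data)
  n_drop <- as.integer(floor(drop_fraction * n + 1e-9))
  if (n - n_drop <= p + 1) {
    stop("retained subsample too small for estimation", call. = FALSE)
  }
  full <- prune_raw(data, alpha)
  ut <- upper.tri(full$weights)
  lin <- which(ut)
  pair_idx <- which(ut, arr.ind = TRUE)

  inc <- matrix(0, n_boot, length(lin))
  wts <- matrix(NA_real_, n_boot, length(lin))
  failed <- logical(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      keep <- if (n_drop > 0) {
        setdiff(seq_len(n), sample.int(n, n_drop))
      } else {
        seq_len(n)
      }
      res <- tryCatch(prune_raw(data[keep, , drop = FALSE], alpha),
                      error = function(e) NULL)
      if (is.null(res)) {
        failed[b] <- TRUE
        next
      }
      w <- res$weights[lin]
      inc[b, ] <- as.numeric(w != 0)
      wts[b, ] <- w
    }
  })
  if (mean(failed) > 0.05) {
    stop(sprintf("%.1f%% of bootstrap replicates failed", 100 * mean(failed)),
         call. = FALSE)
  }
  ok <- !failed
  inclusion <- colMeans(inc[ok, , drop = FALSE])
  qs <- t(apply(wts[ok, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.5, 0.975), na.rm = TRUE))
  items <- colnames(data)
  if (is.null(items)) items <- paste0("V", seq_len(p))
  edge_tab <- data.frame(item_i = items[pair_idx[, 1]],
                         item_j = items[pair_idx[, 2]],
                         full_weight = full$weights[lin],
                         inclusion = inclusion,
                         q025 = qs[, 1], q50 = qs[, 2], q975 = qs[, 3])
  present <- full$weights[lin] != 0
  overall <- if (any(present)) mean(inclusion[present]) else NA_real_
  structure(list(edge_inclusion = edge_tab, overall_recovery = overall,
                 full_network = full, n_boot = n_boot,
                 n_failed = sum(failed), drop_fraction = drop_fraction,
                 alpha = alpha, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("bootstrap_result: %d case-drop replicates ",
                     "(%.0f%% dropped), %d failed\n"),
              x$n_boot, 100 * x$drop_fraction, x$n_failed))
  cat(sprintf("  mean inclusion of full-sample edges: %.4f\n",
              x$overall_recovery))
  invisible(x)
}

#' Write a bootstrap edge summary to CSV
#'
#' @param boot a `bootstrap_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_csv <- function(boot, path) {
  write.csv(boot$edge_inclusion, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-group variability network
#'
#' Edge weights of the variability network are the sample standard deviation
#' (denominator `n_groups - 1`) of each edge across the group networks,
#' treating pruned edges as weight 0 so that presence/absence variation
#' counts.  Node weights are the standard deviation of node expected
#' influence across groups.
#'
#' @param nets list of `pruned_network`s (or weights matrices) over
#'   identical node sets.
#' @param groups optional labels for the networks.
#' @return a `variability_network`: list with `edge_sd` matrix,
#'   `node_ei_sd`, `groups_included`.
#' @export
variability_network <- function(nets, groups = names(nets)) {
  if (length(nets) < 2) stop("need at least 2 networks", call. = FALSE)
  ws <- lapply(nets, function(nt) {
    if (inherits(nt, "pruned_network")) nt$weights else nt
  })
  nm <- colnames(ws[[1]])
  for (w in ws) {
    if (!identical(dim(w), dim(ws[[1]])) || !identical(colnames(w), nm)) {
      stop("networks must share an identical node set", call. = FALSE)
    }
  }
  arr <- simplify2array(ws)  # p x p x k
  edge_sd <- apply(arr, c(1, 2), sd)
  diag(edge_sd) <- 0
  dimnames(edge_sd) <- dimnames(ws[[1]])
  eis <- vapply(ws, colSums, numeric(ncol(ws[[1]])))
  node_sd <- apply(eis, 1, sd)
  names(node_sd) <- nm
  structure(list(edge_sd = edge_sd, node_ei_sd = node_sd,
                 groups_included = groups),
            class = "variability_network")
}

#' Top fraction of most variable edges
#'
#' Edges with nonzero cross-group standard deviation, ranked descending;
#' the top `ceiling(fraction * count)` are returned with bridge labels.
#' Ties are broken by the lexicographic node pair so the ranking is
#' deterministic.
#'
#' @param var a `variability_network`.
#' @param fraction fraction of nonzero-SD edges to keep, in (0, 1].
#' @param community optional item-to-community map for bridge labels.
#' @return data frame `item_i,item_j,sd,is_bridge` in rank order.
#' @export
top_varying_edges <- function(var, fraction = 0.25, community = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  sdm <- var$edge_sd
  idx <- which(upper.tri(sdm) & sdm > 0, arr.ind = TRUE)
  nm <- colnames(sdm)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(sdm)))
  df <- data.frame(item_i = nm[idx[, 1]], item_j = nm[idx[, 2]],
                   sd = sdm[idx])
  df$is_bridge <- if (!is.null(community)) {
    unname(community[df$item_i] != community[df$item_j])
  } else {
    NA
  }
  ord <- order(-df$sd, df$item_i, df$item_j)
  df <- df[ord, , drop = FALSE]
  k <- ceiling(fraction * nrow(df))
  df <- df[seq_len(min(k, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a variability network to CSV and GraphML
#'
#' @param var a `variability_network`.
#' @param csv_path,graphml_path output paths (either may be NULL).
#' @param community optional item-to-community map.
#' @return invisibly, the full edge table.
#' @export
write_variability <- function(var, csv_path = NULL, graphml_path = NULL,
                              community = NULL) {
  tab <- top_varying_edges(var, fraction = 1, community = community)
  if (!is.null(csv_path)) {
    write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(graphml_path)) {
    nm <- colnames(var$edge_sd)
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="sd" for="edge" attr.name="sd" attr.type="double"/>',
      '  <key id="ei_sd" for="node" attr.name="ei_sd" attr.type="double"/>',
      '  <graph edgedefault="undirected">')
    for (i in seq_along(nm)) {
      lines <- c(lines, sprintf(
        '    <node id="%s"><data key="ei_sd">%.10g</data></node>',
        nm[i], var$node_ei_sd[[nm[i]]]))
    }
    for (t in seq_len(nrow(tab))) {
      lines <- c(lines, sprintf(
        '    <edge source="%s" target="%s"><data key="sd">%.10g</data></edge>',
        tab$item_i[t], tab$item_j[t], tab$sd[t]))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, graphml_path)
  }
  invisible(tab)
}
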