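#' Expected influence of each node
#'
#' One-step expected influence: the signed sum of a node's edge weights,
#' distinguishing activating (positive) from deactivating (negative) roles in
#' networks where edges can be negative.
#'
#' @param net a `pruned_network` or a symmetric weights matrix.
#' @return named numeric vector of node expected influence.
#' @export
expected_influence <- function(net) {
  w <- if (inherits(net, "pruned_network")) net$weights else net
  colSums(w)
}

#' Bridge expected influence of each node
#'
#' Signed sum of a node's edges into the other community.  With
#' `normalize = TRUE` (default) the sum is divided by the size of the other
#' community, so that communities with unequal item counts are comparable.
#'
#' @param net a `pruned_network` or weights matrix.
#' @param community named map from item to community label (two communities).
#' @param normalize divide by the other community's node count.
#' @return named numeric vector of bridge expected influence.
#' @export
bridge_expected_influence <- function(net, community = NULL,
                                      normalize = TRUE) {
  w <- if (inherits(net, "pruned_network")) net$weights else net
  if (is.null(community) && inherits(net, "pruned_network")) {
    community <- net$communities
  }
  if (is.null(community)) stop("community map required", call. = FALSE)
  nm <- colnames(w)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(w)))
  if (!all(nm %in% names(community))) {
    stop("unmapped node(s): ",
         paste(setdiff(nm, names(community)), collapse = ", "),
         call. = FALSE)
  }
  comm <- community[nm]
  cross <- outer(comm, comm, "!=")
  raw <- colSums(w * cross)
  if (!normalize) return(raw)
  sizes <- table(comm)
  other_size <- vapply(comm, function(cm) {
    sum(sizes[names(sizes) != cm])
  }, numeric(1))
  raw / other_size
}

#' Within-community expected influence
#'
#' @inheritParams bridge_expected_influence
#' @return named numeric vector: signed sum of each node's edges inside its
#'   own community.
#' @export
within_expected_influence <- function(net, community = NULL) {
  ei <- expected_influence(net)
  ei - bridge_expected_influence(net, community, normalize = FALSE)
}

#' Node and global centrality table
#'
#' Collects per-node expected influence, within-community expected
#' influence, raw and normalized bridge expected influence, and the global
#' aggregates: `ei_global` (sum of node EI, i.e. twice the sum of edge
#' weights) and `ei_bridge_global` (sum of normalized node bridge EI), plus
#' per-community sums and per-node averages.
#'
#' @param net a `pruned_network`.
#' @param community item-to-community map (defaults to the one on `net`).
#' @return a `centrality_table`: data frame with one row per node and
#'   attributes `ei_global`, `ei_bridge_global`, `group_sums`, `group_means`.
#' @export
centrality_table <- function(net, community = net$communities) {
  if (is.null(community)) stop("community map required", call. = FALSE)
  ei <- expected_influence(net)
  br_raw <- bridge_expected_influence(net, community, normalize = FALSE)
  br_norm <- bridge_expected_influence(net, community, normalize = TRUE)
  within <- ei - br_raw
  nm <- names(ei)
  df <- data.frame(item = nm, community = unname(community[nm]),
                   ei = unname(ei), ei_within = unname(within),
                   ei_bridge_raw = unname(br_raw),
                   ei_bridge_norm = unname(br_norm))
  rownames(df) <- NULL
  attr(df, "ei_global") <- sum(ei)
  attr(df, "ei_bridge_global") <- sum(br_norm)
  attr(df, "group_sums") <- tapply(ei, community[nm], sum)
  attr(df, "group_means") <- tapply(ei, community[nm], mean)
  class(df) <- c("centrality_table", "data.frame")
  df
}

#' Global expected-influence indices of a network
#'
#' @inheritParams centrality_table
#' @return list with `ei_global`, `ei_bridge_global`, `group_sums`,
#'   `group_means`.
#' @export
global_indices <- function(net, community = net$communities) {
  tab <- centrality_table(net, community)
  list(ei_global = attr(tab, "ei_global"),
       ei_bridge_global = attr(tab, "ei_bridge_global"),
       group_sums = attr(tab, "group_sums"),
       group_means = attr(tab, "group_means"))
}

#' Write a centrality table to CSV
#'
#' @param tab a `centrality_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
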