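#' Specification of a ground-truth network for simulation
#'
#' Describes a sparse partial-correlation network over two item communities:
#' an intrapersonal community of `n_items_a` items (named `R1...`) and a
#' social-ecological community of `n_items_b` items (named `A1...`).  A
#' fraction `within_density` of the pairs inside each community receive a
#' positive partial correlation; `bridge_count` pairs spanning the two
#' communities receive a bridge edge, of which `negative_bridge_count` are
#' negative.  Edge magnitudes are drawn uniformly from `weight_range`.
#'
#' @param n_items_a,n_items_b community sizes (defaults 10 and 17).
#' @param within_density fraction of within-community pairs with an edge.
#' @param bridge_count number of between-community edges.
#' @param negative_bridge_count how many bridges are negative (others and all
#'   within-community edges are positive).
#' @param weight_range interval of absolute partial correlations.
#' @param seed integer seed controlling edge placement and weights.
#' @return an object of class `true_network_spec`.
#' @export
true_network_spec <- function(n_items_a = 10, n_items_b = 17,
                              within_density = 0.15, bridge_count = 8,
                              negative_bridge_count = 1,
                              weight_range = c(0.1, 0.35), seed = 1) {
  stopifnot(n_items_a >= 1, n_items_b >= 1,
            within_density >= 0, within_density <= 1,
            bridge_count >= 0, negative_bridge_count >= 0,
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[2] < 1, weight_range[1] <= weight_range[2])
  if (negative_bridge_count > bridge_count) {
    stop("negative_bridge_count must not exceed bridge_count", call. = FALSE)
  }
  if (bridge_count > n_items_a * n_items_b) {
    stop("bridge_count exceeds the number of between-community pairs",
         call. = FALSE)
  }
  structure(list(n_items_a = n_items_a, n_items_b = n_items_b,
                 within_density = within_density, bridge_count = bridge_count,
                 negative_bridge_count = negative_bridge_count,
                 weight_range = weight_range, seed = as.integer(seed)),
            class = "true_network_spec")
}

#' Item names and community map for a network spec
#'
#' @param spec a [true_network_spec()].
#' @return named character vector mapping item name to community
#'   (`"A"` = intrapersonal `R` items, `"B"` = social-ecological `A` items).
#' @export
spec_communities <- function(spec) {
  items <- c(paste0("R", seq_len(spec$n_items_a)),
             paste0("A", seq_len(spec$n_items_b)))
  setNames(rep(c("A", "B"), c(spec$n_items_a, spec$n_items_b)), items)
}

#' Build the ground-truth precision matrix for a network spec
#'
#' Constructs a precision matrix whose partial correlations realize the
#' requested sparse structure.  The matrix is first assembled with unit
#' diagonal and off-diagonal entries `-rho[i,j]`; if it is not positive
#' definite, a ridge `delta` is added to the diagonal (doubling from 0.05, at
#' most 20 attempts) until the smallest eigenvalue exceeds 1e-6.  Finally the
#' matrix is rescaled so that its inverse (the latent covariance) has unit
#' diagonal; this rescaling changes neither the zero pattern nor the partial
#' correlations.
#'
#' @param spec a [true_network_spec()].
#' @return the precision matrix with item names, plus attributes
#'   `communities` (item to community map) and `spec`.
#' @export
build_true_precision <- function(spec) {
  stopifnot(inherits(spec, "true_network_spec"))
  pa <- spec$n_items_a
  pb <- spec$n_items_b
  p <- pa + pb
  comm <- spec_communities(spec)
  items <- names(comm)

  with_seed(spec$seed, {
    pairs <- upper_pairs(p)
    is_bridge <- (pairs[, 1] <= pa) != (pairs[, 2] <= pa)
    within_idx <- which(!is_bridge)
    bridge_idx <- which(is_bridge)

    n_within <- round(spec$within_density * length(within_idx))
    if (n_within > length(within_idx)) {
      stop("within_density requests more edges than pairs available",
           call. = FALSE)
    }
    sel_within <- if (n_within > 0) sample(within_idx, n_within) else integer(0)
    sel_bridge <- if (spec$bridge_count > 0) {
      sample(bridge_idx, spec$bridge_count)
    } else {
      integer(0)
    }

    rho <- matrix(0, p, p)
    assign_edge <- function(idx, sign) {
      w <- runif(length(idx), spec$weight_range[1], spec$weight_range[2]) * sign
      for (t in seq_along(idx)) {
        i <- pairs[idx[t], 1]; j <- pairs[idx[t], 2]
        rho[i, j] <<- w[t]; rho[j, i] <<- w[t]
      }
    }
    assign_edge(sel_within, 1)
    if (length(sel_bridge) > 0) {
      signs <- rep(1, length(sel_bridge))
      if (spec$negative_bridge_count > 0) {
        signs[seq_len(spec$negative_bridge_count)] <- -1
      }
      assign_edge(sel_bridge, signs)
    }

    K <- diag(p) - rho  # unit diagonal, off-diagonal -rho => partials = rho

    # positive-definiteness repair by diagonal ridge
    delta <- 0.05
    attempts <- 0
    repeat {
      ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min > 1e-6) break
      attempts <- attempts + 1
      if (attempts > 20) {
        stop("positive-definiteness repair failed after 20 attempts",
             call. = FALSE)
      }
      diag(K) <- diag(K) + delta
      delta <- delta * 2
    }

    # rescale so the implied covariance has unit diagonal
    sigma <- solve(K)
    d <- sqrt(diag(sigma))
    K <- diag(d) %*% K %*% diag(d)
    K <- (K + t(K)) / 2
    dimnames(K) <- list(items, items)
    attr(K, "communities") <- comm
    attr(K, "spec") <- spec
    K
  })
}

#' Partial correlations implied by a precision matrix
#'
#' @param K precision matrix.
#' @return symmetric matrix of partial correlations with zero diagonal.
#' @export
precision_to_partials <- function(K) {
  d <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(d)
  diag(P) <- 0
  dimnames(P) <- dimnames(K)
  P
}

#' Default latent thresholds for 5-point ordinal items
#'
#' Cut-points at the standard-normal quantiles of cumulative probabilities
#' 0.15, 0.40, 0.70, 0.90, giving mildly right-shifted category frequencies
#' typical of agreement-scale responding.
#'
#' @param probs cumulative probabilities of the lower categories.
#' @return numeric vector of strictly increasing cut-points.
#' @export
default_thresholds <- function(probs = c(0.15, 0.40, 0.70, 0.90)) {
  qnorm(probs)
}

#' Sample ordinal item responses from a latent Gaussian network
#'
#' Draws latent vectors from the zero-mean Gaussian whose covariance is the
#' standardized inverse of `precision`, then discretizes each item at the
#' given thresholds into categories `1..(length(thresholds) + 1)`.
#'
#' @param precision positive-definite precision matrix.
#' @param n number of respondents.
#' @param thresholds strictly increasing latent cut-points.
#' @param seed integer seed.
#' @return an `n` by `ncol(precision)` integer matrix of ordinal responses.
#' @export
sample_ordinal_group <- function(precision, n,
                                 thresholds = default_thresholds(), seed = 1) {
  stopifnot(n >= 1, all(diff(thresholds) > 0))
  stop_if_not_pd(precision, "precision matrix")
  sigma <- solve(precision)
  sigma <- stats::cov2cor(sigma)
  R <- chol(sigma)
  with_seed(seed, {
    latent <- rmvnorm_chol(n, R)
    resp <- matrix(1L, n, ncol(precision))
    for (t in thresholds) resp <- resp + (latent > t)
    dimnames(resp) <- list(NULL, colnames(precision))
    resp
  })
}

#' Specification of one simulated group
#'
#' @param group_id unique group label (e.g. a country name).
#' @param network a [true_network_spec()] for the group's ground truth.
#' @param n_respondents number of simulated respondents.
#' @param thresholds latent cut-points shared by all items of the group.
#' @param straightliner_rate fraction of respondents whose rows are replaced
#'   by a single constant response (disengaged "straight-lining").
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(group_id, network, n_respondents,
                       thresholds = default_thresholds(),
                       straightliner_rate = 0) {
  stopifnot(inherits(network, "true_network_spec"), n_respondents >= 1,
            straightliner_rate >= 0, straightliner_rate < 1,
            all(diff(thresholds) > 0))
  structure(list(group_id = as.character(group_id), network = network,
                 n_respondents = as.integer(n_respondents),
                 thresholds = thresholds,
                 straightliner_rate = straightliner_rate),
            class = "group_spec")
}

#' Generate a multi-group synthetic survey study
#'
#' Assembles the full respondent-by-item dataset the pipeline consumes:
#' ordinal responses per group drawn from each group's ground-truth network,
#' group labels, simulated integer ages uniform on `age_range`, simulated sex
#' labels, and the requested fraction of straight-lining respondents (their
#' rows overwritten by one constant category drawn uniformly per respondent).
#' The ground truth (precision matrices, thresholds, seeds) is retained in the
#' `truth` attribute for validation harnesses.
#'
#' @param groups list of [group_spec()] objects with unique `group_id`s.
#' @param age_range inclusive integer age range to simulate.
#' @param p_female probability of the "female" sex label.
#' @param seed master seed; per-group seeds are derived from it.
#' @return a `survey_dataset`: list with `responses` (integer matrix),
#'   `group`, `age`, `sex` (vectors), `community` (item map) and a `truth`
#'   attribute.
#' @export
generate_study <- function(groups, age_range = c(16, 29), p_female = 0.52,
                           seed = 1) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  ids <- vapply(groups, function(g) g$group_id, character(1))
  if (anyDuplicated(ids)) stop("group_ids must be unique", call. = FALSE)

  comm <- spec_communities(groups[[1]]$network)
  n_cat_of <- function(g) length(g$thresholds) + 1L

  resp_list <- list()
  grp <- age <- sex <- list()
  truth <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (!identical(spec_communities(g$network), comm)) {
      stop("all groups must share the same item set", call. = FALSE)
    }
    K <- build_true_precision(g$network)
    gseed <- derive_seed(seed, 7L * k)
    resp <- sample_ordinal_group(K, g$n_respondents, g$thresholds,
                                 seed = gseed)
    n_straight <- as.integer(round(g$straightliner_rate * g$n_respondents))
    demo_seed <- derive_seed(seed, 7L * k + 1L)
    with_seed(demo_seed, {
      if (n_straight > 0) {
        rows <- sample.int(g$n_respondents, n_straight)
        consts <- sample.int(n_cat_of(g), n_straight, replace = TRUE)
        for (t in seq_along(rows)) resp[rows[t], ] <- consts[t]
      }
      age_k <- sample(seq(age_range[1], age_range[2]), g$n_respondents,
                      replace = TRUE)
      sex_k <- ifelse(runif(g$n_respondents) < p_female, "female", "male")
    })
    resp_list[[k]] <- resp
    grp[[k]] <- rep(g$group_id, g$n_respondents)
    age[[k]] <- age_k
    sex[[k]] <- sex_k
    truth[[g$group_id]] <- list(precision = K,
                                partials = precision_to_partials(K),
                                thresholds = g$thresholds, seed = gseed,
                                spec = g$network,
                                straightliner_rate = g$straightliner_rate)
  }

  ds <- structure(list(responses = do.call(rbind, resp_list),
                       group = unlist(grp), age = unlist(age),
                       sex = unlist(sex), community = comm),
                  class = "survey_dataset")
  attr(ds, "truth") <- truth
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset: %d respondents x %d items, %d group(s)\n",
              nrow(x$responses), ncol(x$responses),
              length(unique(x$group))))
  tab <- table(x$group)
  cat(paste(sprintf("  %s: n = %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Write a survey dataset to CSV
#'
#' Wide format with header `respondent_id,group,age,sex,<item columns>`.
#'
#' @param data a `survey_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(data, path) {
  df <- data.frame(respondent_id = seq_len(nrow(data$responses)),
                   group = data$group, age = data$age, sex = data$sex,
                   data$responses, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survey dataset written by [write_survey_csv()]
#'
#' @param path CSV path.
#' @param community optional item to community map; by default items named
#'   `R*` go to community `"A"` and items named `A*` to `"B"`.
#' @return a `survey_dataset`.
#' @export
read_survey_csv <- function(path, community = NULL) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("respondent_id", "group", "age", "sex")
  items <- setdiff(names(df), meta)
  if (is.null(community)) {
    community <- setNames(ifelse(startsWith(items, "R"), "A", "B"), items)
  }
  resp <- as.matrix(df[, items, drop = FALSE])
  storage.mode(resp) <- "integer"
  structure(list(responses = resp, group = as.character(df$group),
                 age = df$age, sex = as.character(df$sex),
                 community = community),
            class = "survey_dataset")
}

#' Write ground truth of a generated study to JSON
#'
#' @param data a `survey_dataset` produced by [generate_study()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(data, path) {
  truth <- attr(data, "truth")
  if (is.null(truth)) stop("dataset carries no ground truth", call. = FALSE)
  out <- lapply(truth, function(t) {
    list(precision = unname(as.matrix(t$precision)),
         thresholds = t$thresholds, seed = t$seed,
         items = colnames(t$precision))
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Perturb a ground-truth precision matrix on absent edges
#'
#' Adds edges with partial correlation `delta` on `n_edges` pairs that are
#' currently zero, producing a second network that differs from the first by
#' exactly those edges.  Useful for power studies of the comparison tests.
#'
#' @param K precision matrix with attribute `communities`.
#' @param n_edges number of absent pairs to turn into edges.
#' @param delta partial correlation given to each new edge.
#' @param seed integer seed for pair selection.
#' @param bridge_only if TRUE, only between-community pairs are eligible.
#' @return the perturbed precision matrix (re-standardized), with attributes
#'   `perturbed_pairs` (2-column matrix of item indices) and `repaired`
#'   (TRUE when a positive-definiteness ridge was needed, in which case all
#'   partials shrink slightly and the difference is no longer exactly
#'   `delta`; choose a sparser base network to avoid this).
#' @export
perturb_precision <- function(K, n_edges, delta, seed = 1,
                              bridge_only = FALSE) {
  comm <- attr(K, "communities")
  P <- precision_to_partials(K)
  p <- ncol(K)
  pairs <- upper_pairs(p)
  absent <- abs(P[pairs]) < 1e-12
  if (bridge_only) {
    stopifnot(!is.null(comm))
    absent <- absent & (comm[pairs[, 1]] != comm[pairs[, 2]])
  }
  cand <- which(absent)
  if (length(cand) < n_edges) {
    stop("not enough absent pairs to perturb", call. = FALSE)
  }
  with_seed(seed, {
    sel <- sample(cand, n_edges)
  })
  rho <- P
  for (t in sel) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    rho[i, j] <- rho[j, i] <- delta
  }
  K2 <- diag(p) - rho
  delta_r <- 0.05
  attempts <- 0
  repeat {
    ev_min <- min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min > 1e-6) break
    attempts <- attempts + 1
    if (attempts > 20) stop("PD repair failed", call. = FALSE)
    diag(K2) <- diag(K2) + delta_r
    delta_r <- delta_r * 2
  }
  repaired <- attempts > 0
  sigma <- solve(K2)
  d <- sqrt(diag(sigma))
  K2 <- diag(d) %*% K2 %*% diag(d)
  K2 <- (K2 + t(K2)) / 2
  dimnames(K2) <- dimnames(K)
  attr(K2, "communities") <- comm
  attr(K2, "perturbed_pairs") <- pairs[sel, , drop = FALSE]
  attr(K2, "repaired") <- repaired
  K2
}
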