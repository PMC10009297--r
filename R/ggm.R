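#' Estimate an item correlation matrix
#'
#' @param data respondent-by-item numeric matrix (or a `survey_dataset`, in
#'   which case its response matrix is used).
#' @param method one of `"pearson"` (default, raw ordinal scores treated as
#'   continuous), `"spearman"`, or `"polychoric"` (two-step latent-Gaussian
#'   estimate for ordinal items).
#' @return a `correlation_estimate`: list with `matrix`, `n`, `method`.  If
#'   the matrix has negative eigenvalues beyond numerical noise it is
#'   repaired to the nearest positive semi-definite matrix by eigenvalue
#'   clipping, with a warning.
#' @export
estimate_correlations <- function(data, method = c("pearson", "spearman",
                                                   "polychoric")) {
  method <- match.arg(method)
  if (inherits(data, "survey_dataset")) data <- data$responses
  data <- as.matrix(data)
  vars <- apply(data, 2, var)
  if (any(vars == 0)) {
    bad <- colnames(data)[vars == 0]
    if (is.null(bad)) bad <- which(vars == 0)
    stop(sprintf("zero-variance item(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(data)
  if (n <= ncol(data)) {
    stop("need more respondents than items", call. = FALSE)
  }
  R <- switch(method,
              pearson = cor(data),
              spearman = cor(data, method = "spearman"),
              polychoric = polychoric_matrix(data))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warning("correlation matrix not PSD; repaired by eigenvalue clipping")
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor((R + t(R)) / 2)
    dimnames(R) <- list(colnames(data), colnames(data))
  }
  structure(list(matrix = R, n = n, method = method),
            class = "correlation_estimate")
}

# Bivariate standard normal rectangle probability P(X <= a, Y <= b) by
# one-dimensional quadrature of phi(x) * Phi((b - rho x)/sqrt(1 - rho^2)).
pbinorm <- function(a, b, rho) {
  if (!is.finite(a) && a < 0) return(0)
  if (!is.finite(b) && b < 0) return(0)
  if (!is.finite(a)) return(pnorm(b))
  if (!is.finite(b)) return(pnorm(a))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * pnorm((b - rho * x) / s),
                   -Inf, a, rel.tol = 1e-9)$value
}

# Two-step polychoric correlation for one ordinal pair: thresholds from the
# marginal cumulative proportions, then profile ML over rho.
polychoric_pair <- function(x, y) {
  thr <- function(v) {
    tab <- cumsum(table(factor(v, levels = sort(unique(v)))))
    n <- length(v)
    qnorm(utils::head(tab, -1) / n)
  }
  tx <- c(-Inf, thr(x), Inf)
  ty <- c(-Inf, thr(y), Inf)
  lx <- sort(unique(x)); ly <- sort(unique(y))
  counts <- table(factor(x, levels = lx), factor(y, levels = ly))
  nll <- function(rho) {
    ll <- 0
    for (i in seq_along(lx)) {
      for (j in seq_along(ly)) {
        if (counts[i, j] == 0) next
        pr <- pbinorm(tx[i + 1], ty[j + 1], rho) -
          pbinorm(tx[i], ty[j + 1], rho) -
          pbinorm(tx[i + 1], ty[j], rho) + pbinorm(tx[i], ty[j], rho)
        ll <- ll + counts[i, j] * log(max(pr, 1e-300))
      }
    }
    -ll
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

polychoric_matrix <- function(data) {
  p <- ncol(data)
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <- polychoric_pair(data[, i], data[, j])
    }
  }
  dimnames(R) <- list(colnames(data), colnames(data))
  R
}

#' Saturated partial correlation network
#'
#' Partials from the standardized inverse correlation matrix:
#' `w_ij = -k_ij / sqrt(k_ii * k_jj)` with zero diagonal.
#'
#' @param corr a `correlation_estimate` or a plain correlation matrix.
#' @return symmetric matrix of partial correlations.
#' @export
saturated_partials <- function(corr) {
  R <- if (inherits(corr, "correlation_estimate")) corr$matrix else corr
  K <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; saturated partials undefined",
         call. = FALSE)
  })
  precision_to_partials(K)
}

#' Fisher-z p-values for partial correlation edges
#'
#' Two-sided p from `z = atanh(w) * sqrt(n - k - 3)` where `k = n_items - 2`
#' is the size of the conditioning set of each partial correlation.
#'
#' @param partials edge matrix of partial correlations.
#' @param n sample size.
#' @param n_items number of variables in the network (defaults to the matrix
#'   dimension).
#' @return symmetric p-value matrix with unit diagonal.
#' @export
edge_pvalues <- function(partials, n, n_items = ncol(partials)) {
  df <- n - n_items - 1  # n - (k = p - 2) - 3
  if (df <= 0) stop("sample too small for edge tests", call. = FALSE)
  z <- suppressWarnings(atanh(partials)) * sqrt(df)
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- 0
  diag(p) <- 1
  p
}

#' Fit a Gaussian graphical model with zero constraints
#'
#' Covariance selection: finds the implied covariance `Sigma` that matches
#' `S` on the diagonal and on every retained pair while `solve(Sigma)` is
#' exactly zero on the constrained pairs.  Solved by cycling coordinate-wise
#' regression updates (the regression form of iterative proportional
#' fitting); convergence when the largest absolute change in `Sigma` over a
#' sweep is below `tol`.
#'
#' @param S correlation (or covariance) matrix, positive definite.
#' @param zero_pattern constrained pairs: either a logical matrix (TRUE =
#'   precision forced to zero) or a 2-column index matrix.
#' @param n sample size, used for the log-likelihood.
#' @param tol convergence tolerance on `Sigma` entries.
#' @param max_sweeps sweep cap before aborting.
#' @return list with `sigma` (implied covariance), `precision`, `partials`,
#'   `logL` (Gaussian log-likelihood at `sigma`), `converged`, `sweeps`.
#' @export
fit_constrained_ggm <- function(S, zero_pattern, n, tol = 1e-8,
                                max_sweeps = 1000) {
  if (inherits(S, "correlation_estimate")) {
    if (missing(n)) n <- S$n
    S <- S$matrix
  }
  p <- ncol(S)
  stop_if_not_pd(S, "input matrix S")
  zp <- matrix(FALSE, p, p)
  if (is.matrix(zero_pattern) && is.logical(zero_pattern)) {
    zp <- zero_pattern | t(zero_pattern)
  } else if (is.matrix(zero_pattern) && ncol(zero_pattern) == 2) {
    for (t in seq_len(nrow(zero_pattern))) {
      zp[zero_pattern[t, 1], zero_pattern[t, 2]] <- TRUE
      zp[zero_pattern[t, 2], zero_pattern[t, 1]] <- TRUE
    }
  } else if (length(zero_pattern) == 0) {
    # empty pattern: saturated model
  } else {
    stop("zero_pattern must be a logical matrix or a 2-column index matrix",
         call. = FALSE)
  }
  diag(zp) <- FALSE
  free_adj <- !zp
  diag(free_adj) <- FALSE
  fit <- .cpp_ggm_fit(S, matrix(as.integer(free_adj), p, p), tol,
                      as.integer(max_sweeps))
  if (!fit$converged) {
    stop(sprintf("constrained fit did not converge (attained %.3e > %.1e)",
                 fit$final_change, tol), call. = FALSE)
  }
  dimnames(fit$sigma) <- dimnames(fit$precision) <-
    dimnames(fit$partials) <- dimnames(S)
  logL <- gaussian_loglik(S, fit$sigma, n)
  list(sigma = fit$sigma, precision = fit$precision,
       partials = fit$partials, logL = logL, converged = fit$converged,
       sweeps = fit$sweeps)
}

gaussian_loglik <- function(S, sigma, n) {
  p <- ncol(S)
  -0.5 * n * (p * log(2 * pi) + determinant(sigma)$modulus[1] +
                sum(diag(solve(sigma, S))))
}

#' SEM-style fit indices for a pruned network model
#'
#' Discrepancy `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`; test statistic
#' `T = (n - 1) F`; RMSEA, CFI, TLI against the independence baseline
#' (diagonal covariance, `df_b = p(p-1)/2`); `BIC = -2 logL + q log n` with
#' `q = p + number of retained edges`.
#'
#' @param logL_model Gaussian log-likelihood of the fitted model.
#' @param S sample correlation matrix.
#' @param sigma model-implied covariance.
#' @param n sample size.
#' @param df degrees of freedom (number of pruned edges).
#' @return list of class `fit_indices`.
#' @export
fit_indices <- function(logL_model, S, sigma, n, df) {
  p <- ncol(S)
  Fdisc <- determinant(sigma)$modulus[1] + sum(diag(solve(sigma, S))) -
    determinant(S)$modulus[1] - p
  Fdisc <- max(Fdisc, 0)
  Tstat <- (n - 1) * Fdisc
  rmsea <- if (df > 0) sqrt(max(Tstat - df, 0) / (df * (n - 1))) else 0

  # independence baseline: diagonal covariance
  Fb <- -determinant(S)$modulus[1]
  Tb <- (n - 1) * Fb
  dfb <- p * (p - 1) / 2
  cfi_den <- max(Tb - dfb, Tstat - df, 0)
  cfi <- if (cfi_den > 0) 1 - max(Tstat - df, 0) / cfi_den else 1
  tli_note <- NULL
  if (df > 0 && dfb > 0 && Tb > dfb) {
    tli <- ((Tb / dfb) - (Tstat / df)) / ((Tb / dfb) - 1)
    if (tli > 1) tli_note <- "TLI exceeded 1 (chi-square below df)"
  } else {
    tli <- 1
    if (df == 0) tli_note <- "df = 0; TLI reported as 1"
  }
  q <- p + (p * (p - 1) / 2 - df)
  bic <- -2 * logL_model + q * log(n)
  structure(list(chi_square = Tstat, df = df, bic = bic, rmsea = rmsea,
                 cfi = cfi, tli = tli, log_likelihood = logL_model,
                 note = tli_note),
            class = "fit_indices")
}

#' Estimate a pruned partial correlation network
#'
#' Recursive significance pruning of the saturated Gaussian graphical model:
#' the saturated partials are tested by Fisher z, all edges with `p >= alpha`
#' are removed at once, the constrained model is refit by covariance
#' selection, the implied partials are retested, and the cycle repeats until
#' a round removes nothing.  Pruned edges are never re-added.
#'
#' @param corr a `correlation_estimate` (see [estimate_correlations()]), or a
#'   correlation matrix (then `n` must be given).
#' @param alpha edge significance level (default 0.05).
#' @param n sample size when `corr` is a plain matrix.
#' @param communities optional item-to-community map stored on the result.
#' @param tol,max_sweeps constrained-fit controls.
#' @return a `pruned_network`: list with `weights` (partial correlations,
#'   zeros on pruned pairs), `zero_pattern` (logical matrix), `sigma`
#'   (implied covariance), `precision`, `n`, `alpha`, `iterations`, `fit`
#'   (a [fit_indices()] object).
#' @export
prune_network <- function(corr, alpha = 0.05, n = NULL, communities = NULL,
                          tol = 1e-8, max_sweeps = 1000) {
  if (inherits(corr, "correlation_estimate")) {
    S <- corr$matrix
    n <- corr$n
  } else {
    S <- corr
    if (is.null(n)) stop("n must be supplied with a plain matrix",
                         call. = FALSE)
  }
  p <- ncol(S)
  if (n - p - 1 <= 0) stop("sample too small for edge tests", call. = FALSE)
  res <- .cpp_prune(S, as.integer(n), alpha, tol, as.integer(max_sweeps))
  weights <- res$weights
  zero_pattern <- res$free_adj == 0
  diag(zero_pattern) <- FALSE
  dimnames(weights) <- dimnames(zero_pattern) <- dimnames(S)
  df <- sum(zero_pattern[upper.tri(zero_pattern)])
  logL <- gaussian_loglik(S, res$sigma, n)
  fit <- fit_indices(logL, S, res$sigma, n, df)
  sigma <- res$sigma
  precision <- res$precision
  dimnames(sigma) <- dimnames(precision) <- dimnames(S)
  structure(list(weights = weights, zero_pattern = zero_pattern,
                 sigma = sigma, precision = precision, n = n, alpha = alpha,
                 iterations = res$iterations, fit = fit,
                 communities = communities),
            class = "pruned_network")
}

#' @export
print.pruned_network <- function(x, ...) {
  p <- ncol(x$weights)
  n_edges <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(paste0("pruned_network: %d nodes, %d edges retained of %d ",
                     "(alpha = %g, %d pruning rounds)\n"),
              p, n_edges, p * (p - 1) / 2, x$alpha, x$iterations))
  cat(sprintf("  fit: chi2 = %.2f (df = %d), BIC = %.2f, RMSEA = %.3f, ",
              x$fit$chi_square, x$fit$df, x$fit$bic, x$fit$rmsea))
  cat(sprintf("CFI = %.3f, TLI = %.3f\n", x$fit$cfi, x$fit$tli))
  invisible(x)
}

#' Export a pruned network as an edge list
#'
#' @param net a `pruned_network` with a community map (or supply one).
#' @param path optional CSV path; when given the edge list is written with
#'   header `item_i,item_j,weight,is_bridge`.
#' @param communities item-to-community map overriding the one on `net`.
#' @return the edge-list data frame, invisibly when writing.
#' @export
network_edgelist <- function(net, path = NULL, communities = net$communities) {
  w <- net$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  nm <- colnames(w)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(w)))
  is_bridge <- if (!is.null(communities)) {
    communities[nm[idx[, 1]]] != communities[nm[idx[, 2]]]
  } else {
    rep(NA, nrow(idx))
  }
  df <- data.frame(item_i = nm[idx[, 1]], item_j = nm[idx[, 2]],
                   weight = w[idx], is_bridge = unname(is_bridge))
  df <- df[order(df$item_i, df$item_j), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a pruned network to GraphML
#'
#' Nodes carry a `community` attribute; edges carry `weight` and `is_bridge`.
#'
#' @param net a `pruned_network`.
#' @param path output file path.
#' @param communities item-to-community map.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, communities = net$communities) {
  w <- net$weights
  nm <- colnames(w)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(w)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="community" for="node" attr.name="community" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="is_bridge" for="edge" attr.name="is_bridge" attr.type="boolean"/>',
    '  <graph edgedefault="undirected">')
  for (i in seq_along(nm)) {
    cm <- if (!is.null(communities)) communities[[nm[i]]] else ""
    lines <- c(lines, sprintf('    <node id="%s"><data key="community">%s</data></node>',
                              nm[i], cm))
  }
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  for (t in seq_len(nrow(idx))) {
    i <- idx[t, 1]; j <- idx[t, 2]
    br <- if (!is.null(communities)) {
      tolower(communities[[nm[i]]] != communities[[nm[j]]])
    } else "false"
    lines <- c(lines, sprintf(
      paste0('    <edge source="%s" target="%s">',
             '<data key="weight">%.10g</data>',
             '<data key="is_bridge">%s</data></edge>'),
      nm[i], nm[j], w[i, j], br))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
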