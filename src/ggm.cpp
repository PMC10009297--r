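// Covariance selection (Gaussian graphical model with zero constraints on the
// precision matrix) and recursive significance pruning.
//
// The constrained fit uses the regression sweep form of iterative proportional
// fitting: cycle over variables, and for each variable solve the restricted
// regression of that variable on its free partners in the current implied
// covariance W.  At convergence W matches S on the diagonal and on all free
// pairs, while the precision K = W^{-1} is exactly zero on constrained pairs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One full fit.  free_adj is a symmetric 0/1 matrix over off-diagonal pairs.
// W is used as the starting value (warm start) and overwritten.
static bool fit_sweeps(const mat &S, const umat &free_adj, mat &W,
                       double tol, int max_sweeps, int &sweeps_used,
                       double &final_change) {
  const uword p = S.n_rows;
  W.diag() = S.diag();

  // free partner index list per variable
  std::vector<uvec> partners(p);
  for (uword j = 0; j < p; ++j) {
    std::vector<uword> idx;
    for (uword i = 0; i < p; ++i)
      if (i != j && free_adj(i, j)) idx.push_back(i);
    partners[j] = conv_to<uvec>::from(idx);
  }

  double maxdiff = datum::inf;
  int sweep = 0;
  for (; sweep < max_sweeps && maxdiff > tol; ++sweep) {
    maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec &idx = partners[j];
      vec w_new(p, fill::zeros);
      if (idx.n_elem > 0) {
        mat W11 = W(idx, idx);
        vec s12 = S.col(j);
        vec beta;
        if (!solve(beta, W11, s12.elem(idx), solve_opts::likely_sympd))
          return false;
        // w12 = W[, idx] %*% beta over all rows except j
        vec full = W.cols(idx) * beta;
        w_new = full;
      }
      w_new(j) = W(j, j);
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::abs(w_new(i) - W(i, j));
        if (d > maxdiff) maxdiff = d;
        W(i, j) = w_new(i);
        W(j, i) = w_new(i);
      }
    }
  }
  sweeps_used = sweep;
  final_change = maxdiff;
  return maxdiff <= tol;
}

// Recover precision K from converged W, with exact zeros on constrained pairs.
static mat precision_from_fit(const mat &S, const umat &free_adj, const mat &W) {
  const uword p = S.n_rows;
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    std::vector<uword> idxv;
    for (uword i = 0; i < p; ++i)
      if (i != j && free_adj(i, j)) idxv.push_back(i);
    uvec idx = conv_to<uvec>::from(idxv);
    double kjj;
    if (idx.n_elem == 0) {
      kjj = 1.0 / W(j, j);
      K(j, j) = kjj;
      continue;
    }
    mat W11 = W(idx, idx);
    vec s12 = S.col(j);
    vec beta = solve(W11, s12.elem(idx), solve_opts::likely_sympd);
    double quad = 0.0;
    for (uword t = 0; t < idx.n_elem; ++t) quad += W(idx(t), j) * beta(t);
    kjj = 1.0 / (W(j, j) - quad);
    K(j, j) = kjj;
    for (uword t = 0; t < idx.n_elem; ++t) {
      K(idx(t), j) = -beta(t) * kjj;
    }
  }
  // symmetrize (entries computed twice, once per endpoint)
  K = 0.5 * (K + K.t());
  return K;
}

static mat partials_from_precision(const mat &K) {
  vec d = 1.0 / sqrt(K.diag());
  mat P = -(K % (d * d.t()));
  P.diag().zeros();
  return P;
}

// [[Rcpp::export(name = ".cpp_ggm_fit")]]
Rcpp::List cpp_ggm_fit(const arma::mat &S, const arma::umat &free_adj,
                       double tol, int max_sweeps) {
  mat W = S;  // start from the saturated solution
  int sweeps = 0;
  double change = 0.0;
  bool conv = fit_sweeps(S, free_adj, W, tol, max_sweeps, sweeps, change);
  mat K = precision_from_fit(S, free_adj, W);
  mat P = partials_from_precision(K);
  return Rcpp::List::create(
      Rcpp::Named("sigma") = W, Rcpp::Named("precision") = K,
      Rcpp::Named("partials") = P, Rcpp::Named("converged") = conv,
      Rcpp::Named("sweeps") = sweeps, Rcpp::Named("final_change") = change);
}

// Recursive pruning: test edges by Fisher z on the (implied) partials,
// remove all non-significant edges at once, refit, retest; stop when a
// round removes nothing.  Pruned edges are never re-added.
// [[Rcpp::export(name = ".cpp_prune")]]
Rcpp::List cpp_prune(const arma::mat &S, int n, double alpha, double tol,
                     int max_sweeps) {
  const uword p = S.n_rows;
  const double se_df = std::sqrt((double)n - (double)p - 1.0);

  mat K0;
  if (!inv_sympd(K0, S))
    Rcpp::stop("correlation matrix is singular; cannot form saturated partials");
  mat partials = partials_from_precision(K0);

  umat free_adj(p, p, fill::ones);
  free_adj.diag().zeros();

  mat W = S;  // implied covariance of the current model (saturated at start)
  mat K = K0;
  int iterations = 0;
  bool any_removed_total = false;

  for (int round = 0; round < (int)(p * p); ++round) {
    // test retained edges
    uword removed = 0;
    for (uword i = 0; i < p; ++i) {
      for (uword j = i + 1; j < p; ++j) {
        if (!free_adj(i, j)) continue;
        double w = partials(i, j);
        if (std::abs(w) >= 1.0) continue;  // infinitely significant
        double z = std::atanh(w) * se_df;
        double pval = 2.0 * R::pnorm(-std::abs(z), 0.0, 1.0, 1, 0);
        if (pval >= alpha) {
          free_adj(i, j) = 0;
          free_adj(j, i) = 0;
          ++removed;
        }
      }
    }
    ++iterations;
    if (removed == 0) break;
    any_removed_total = true;
    int sweeps = 0;
    double change = 0.0;
    bool conv = fit_sweeps(S, free_adj, W, tol, max_sweeps, sweeps, change);
    if (!conv)
      Rcpp::stop("constrained fit did not converge in pruning round %d "
                 "(attained %.3e)", iterations, change);
    K = precision_from_fit(S, free_adj, W);
    partials = partials_from_precision(K);
    // zero out pruned pairs exactly
    partials.elem(find(free_adj == 0)).zeros();
    partials.diag().zeros();
  }

  mat weights = partials;
  weights.elem(find(free_adj == 0)).zeros();
  weights.diag().zeros();

  if (!any_removed_total) {
    W = S;
    K = K0;
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = weights, Rcpp::Named("sigma") = W,
      Rcpp::Named("precision") = K, Rcpp::Named("free_adj") = free_adj,
      Rcpp::Named("iterations") = iterations);
}
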