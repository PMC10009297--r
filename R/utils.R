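#' @useDynLib resilnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor var sd qnorm pnorm rnorm runif optim quantile setNames
#' @importFrom utils write.csv read.csv
NULL

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a sub-stage seed from a master seed
#'
#' Stages of the pipeline (estimation, comparisons, bootstrap, ...) each draw
#' their own seed from the master seed through a fixed counter scheme, so any
#' stage can be re-run in isolation and still reproduce its numbers.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer stage counter.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  # multiplicative hash, kept inside 31 bits
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807 + 11) %%
               2147483647)
}

# Multivariate normal draws given an upper-triangular Cholesky factor.
rmvnorm_chol <- function(n, chol_upper) {
  p <- ncol(chol_upper)
  matrix(rnorm(n * p), n, p) %*% chol_upper
}

is_square_sym <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) < tol
}

stop_if_not_pd <- function(m, what = "matrix") {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("%s is not positive definite (min eigenvalue %.3e)",
                 what, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

# upper-triangle index pairs of a p x p matrix as a 2-column matrix
upper_pairs <- function(p) {
  which(upper.tri(diag(p)), arr.ind = TRUE)
}
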