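#' Blomberg's K statistic of phylogenetic signal
#'
#' The observed ratio of among-species variance (around the phylogenetic GLS
#' mean) to the phylogenetically corrected variance, standardized by its
#' Brownian-motion expectation:
#' `K = [MSE0/MSE] / [(tr(C) - n/(1' C^-1 1)) / (n - 1)]`,
#' where `MSE0 = (x - a)'(x - a)/(n-1)`, `MSE = (x - a)' C^-1 (x - a)/(n-1)`
#' and `a` is the GLS phylogenetic mean. `K = 1` is the BM expectation;
#' `K = 1` exactly on a star tree for any data.
#'
#' @param x Named numeric vector of tip values.
#' @param tree A `"phylo"` object.
#' @param C Optional precomputed shared-time matrix.
#' @return K (scalar), or `NA` with a warning for constant data.
#' @export
blomberg_k <- function(x, tree, C = NULL) {
  if (is.null(C)) {
    x <- align_tips(x, tree)
    C <- shared_time_matrix(tree)
  } else if (!is.null(names(x)) && !is.null(rownames(C))) {
    x <- x[rownames(C)]
  }
  n <- length(x)
  if (n < 4) stop("need at least 4 tips for K")
  L <- tryCatch(chol(C), error = function(e) stop("singular covariance matrix"))
  ones <- rep(1, n)
  w1 <- backsolve(L, ones, transpose = TRUE)
  wx <- backsolve(L, x, transpose = TRUE)
  sum1 <- sum(w1^2)                 # 1' C^-1 1
  a <- sum(w1 * wx) / sum1          # GLS phylogenetic mean
  mse0 <- sum((x - a)^2)
  mse <- sum((wx - a * w1)^2)
  if (mse < .Machine$double.eps * n) {
    warning("constant trait values: K undefined")
    return(NA_real_)
  }
  expected <- (sum(diag(C)) - n / sum1) / (n - 1)
  (mse0 / mse) / expected
}

#' Pagel's lambda by profile maximum likelihood
#'
#' The lambda transform multiplies the off-diagonal entries of the
#' phylogenetic covariance matrix by `lambda`, leaving the diagonal
#' unchanged; `lambda = 0` gives a star-like (no-signal) structure and
#' `lambda = 1` the untransformed tree. The estimate maximizes the Gaussian
#' profile likelihood (root state and rate profiled by GLS) over
#' `[0, lambda_max]`, where `lambda_max` is the largest value keeping the
#' transformed matrix positive definite (>= 1 on ultrametric trees).
#'
#' @inheritParams blomberg_k
#' @return A list with `lambda`, `loglik`, `lambda_max`, and boundary flags
#'   `at_zero` / `at_max`.
#' @export
pagel_lambda <- function(x, tree, C = NULL) {
  if (is.null(C)) {
    x <- align_tips(x, tree)
    C <- shared_time_matrix(tree)
  } else if (!is.null(names(x)) && !is.null(rownames(C))) {
    x <- x[rownames(C)]
  }
  n <- length(x)
  if (n < 4) stop("need at least 4 tips for lambda")
  offmax <- max(C[upper.tri(C)])
  lmax <- if (offmax <= 0) 1 else min(diag(C)) / offmax
  pd_ok <- function(l) !inherits(tryCatch(chol(lambda_transform(C, l)),
                                          error = identity), "error")
  while (lmax > 1e-8 && !pd_ok(lmax)) lmax <- lmax * 0.95
  obj <- function(l) gls_profile(x, lambda_transform(C, l))$loglik
  opt <- profile_optimize(obj, lower = 0, upper = lmax,
                          starts = c(0.25, 0.5, 0.9) * lmax)
  list(lambda = opt$par, loglik = opt$value, lambda_max = lmax,
       at_zero = opt$par < 1e-6 * lmax, at_max = (lmax - opt$par) < 1e-6 * lmax)
}

#' Lambda transform of a phylogenetic covariance matrix
#'
#' Off-diagonal entries are multiplied by `lambda`; the diagonal is left
#' unchanged.
#'
#' @param C Covariance matrix.
#' @param lambda Scaling in `[0, lambda_max]`.
#' @export
lambda_transform <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}
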