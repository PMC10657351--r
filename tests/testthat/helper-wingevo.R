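## Shared fixtures for the test suite; everything is built in code.

## A data matrix whose sample covariance equals Sigma exactly:
## start from any full-rank residual matrix, whiten it to exact identity
## sample covariance, then color by chol(Sigma).
exact_cov_data <- function(Sigma, n = nrow(Sigma) * 3, seed = 1) {
  set.seed(seed)
  p <- nrow(Sigma)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- Z %*% solve(chol(cov(Z)))
  W %*% chol(Sigma)
}

## Two-module factor data: variables within a module load on a shared
## factor, factors across modules are made exactly sample-orthogonal, so
## the between-module sample covariance of the noiseless part is zero.
modular_factor_data <- function(n = 60, p1 = 10, p2 = 12, noise_sd = 0.1,
                                seed = 1) {
  set.seed(seed)
  f1 <- scale(rnorm(n))
  f2 <- resid(lm(rnorm(n) ~ f1))        # exactly orthogonal to f1, centered
  f2 <- f2 / sd(f2)
  X1 <- f1 %*% t(runif(p1, 0.5, 1.5))
  X2 <- f2 %*% t(runif(p2, 0.5, 1.5))
  X <- cbind(X1, X2)
  if (noise_sd > 0) X <- X + matrix(rnorm(n * (p1 + p2), sd = noise_sd), n)
  rownames(X) <- sprintf("sp%03d", seq_len(n))
  list(data = X, partition = rep(c("A", "B"), c(p1, p2)))
}

## Small reference trees used across tests.
tree_abc <- function() read_newick("((A:1,B:1):1,C:2);")

star_tree <- function(n = 8, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr
}

## Dense rectangular slice cloud (solid fill).
rect_slice <- function(n = 4000, ylim = c(0, 40), zlim = c(0, 2), seed = 5) {
  set.seed(seed)
  cbind(runif(n, 0, 10), runif(n, ylim[1], ylim[2]), runif(n, zlim[1], zlim[2]))
}
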