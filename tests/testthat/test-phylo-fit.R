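test_that("log-likelihood matches the Gaussian density", {
  ## standard normal at its mean
  expect_equal(phylo_loglik(0, matrix(1), 0), -0.5 * log(2 * pi))

  ## zero quadratic form leaves -(n/2)log(2pi) - log|V|/2
  V <- diag(3) + 0.2
  expect_equal(phylo_loglik(rep(2, 3), V, 2),
               -1.5 * log(2 * pi) - 0.5 * log(det(V)))

  ## 3-taxon tree vs brute-force inverse-based density
  tr <- tree_abc()
  C <- phylo_cov(tr, "BM")
  x <- c(A = 0, B = 1, C = 4)[rownames(C)]
  e <- x - 1
  brute <- -0.5 * (3 * log(2 * pi) + log(det(C)) +
                   drop(t(e) %*% solve(C) %*% e))
  expect_equal(phylo_loglik(x, C, 1), brute)
  expect_error(phylo_loglik(x, matrix(-1, 3, 3), 0), "positive definite")
})

test_that("BM fit matches the GLS closed form", {
  t2 <- read_newick("(A:1,B:1);")
  f <- fit_model(c(A = 1, B = -1), t2, "BM")
  expect_equal(f$z0, 0)
  expect_equal(f$sigma2, 1)

  ## constant data: rate collapses to zero with a degenerate flag
  tr <- simulate_tree(8, seed = 1)
  x <- rep(3, 8); names(x) <- tr$tip.label
  fc <- fit_model(x, tr, "BM")
  expect_equal(fc$sigma2, 0)
  expect_true(fc$degenerate)
  expect_true(is.finite(fc$loglik))
})

test_that("BM likelihood is invariant to tip order and equivariant to scale", {
  tr <- simulate_tree(12, seed = 2)
  x <- simulate_traits(tr, 0.3, cross_slice_corr = 0, seed = 3)$values[, 1]
  f1 <- fit_model(x, tr, "BM")
  f2 <- fit_model(x[rev(names(x))], tr, "BM")
  expect_equal(f1$loglik, f2$loglik)
  expect_equal(f1$sigma2, f2$sigma2)
  f4 <- fit_model(2 * x, tr, "BM")
  expect_equal(f4$sigma2, 4 * f1$sigma2, tolerance = 1e-10)
})

test_that("GLS mean equals the arithmetic mean on a star tree", {
  st <- star_tree(10)
  set.seed(3)
  x <- rnorm(10); names(x) <- st$tip.label
  expect_equal(fit_model(x, st, "BM")$z0, mean(x), tolerance = 1e-10)
})

test_that("AICc arithmetic and model selection behave", {
  expect_equal(aicc(-10, 2, 178), 24 + 12 / 175)
  expect_error(aicc(-10, 3, 4), "undefined")

  ## identical likelihoods: parsimony tie-break picks the 2-parameter model
  tr <- simulate_tree(24, seed = 9)
  x <- simulate_traits(tr, 1, cross_slice_corr = 0, seed = 9)$values[, 1]
  fb <- fit_model(x, tr, "BM")
  fake_ou <- fb; fake_ou$model <- "OU"; fake_ou$n_params <- 3L
  fake_ou$aicc <- aicc(fb$loglik, 3, fb$n)
  sel <- model_select(list(fake_ou, fb))
  expect_equal(sel$best$model, "BM")
  expect_equal(sel$table$delta_aicc[1], 0)
})

test_that("BM rate is recovered without bias on simulated data", {
  ## oracle: simulation consistency of the ML estimator
  tr <- simulate_tree(128, seed = 6)
  C <- phylo_cov(tr, "BM")
  U <- chol(C)
  set.seed(6)
  s2 <- replicate(200, {
    x <- drop(crossprod(U, rnorm(128))) * sqrt(0.5)
    names(x) <- rownames(C)
    fit_model(x, tr, "BM", C = C)$sigma2
  })
  expect_lt(abs(mean(s2) - 0.5) / 0.5, 0.05)
})

test_that("OU and EB parameters are recovered at adequate sample size", {
  ## ML for alpha and r carries finite-sample bias that vanishes with n;
  ## at 256 tips the median estimate sits within 10% of the truth
  n <- 256
  tr <- simulate_tree(n, seed = 6)
  C <- phylo_cov(tr, "BM")
  Vou <- phylo_cov(tr, "OU", alpha = 2); Uou <- chol(Vou)
  set.seed(61)
  ah <- replicate(100, {
    x <- drop(crossprod(Uou, rnorm(n))); names(x) <- rownames(Vou)
    fit_model(x, tr, "OU", C = C)$alpha
  })
  expect_lt(abs(median(ah) - 2) / 2, 0.10)

  Veb <- phylo_cov(tr, "EB", r_eb = -2); Ueb <- chol(Veb)
  set.seed(62)
  rh <- replicate(100, {
    x <- drop(crossprod(Ueb, rnorm(n))); names(x) <- rownames(Veb)
    fit_model(x, tr, "EB", C = C)$r_eb
  })
  expect_lt(abs(median(rh) + 2) / 2, 0.10)
})

test_that("sigma2 profile tracks a spanwise rate gradient", {
  tr <- simulate_tree(128, seed = 5)
  s2_true <- ((1:35) / 35)^2 * 0.001 + 1e-5
  pr <- simulate_traits(tr, s2_true, cross_slice_corr = 0.8, mu = 0.1,
                        seed = 11)
  prof <- sigma2_profile(pr, tr)
  expect_equal(nrow(prof), 35)
  expect_gt(cor(prof$value, s2_true, method = "spearman"), 0.9)

  ## scale equivariance slice by slice
  pr2 <- pr; pr2$values <- 2 * pr$values
  prof2 <- sigma2_profile(pr2, tr, model_policy = "BM")
  prof1 <- sigma2_profile(pr, tr, model_policy = "BM")
  expect_equal(prof2$value, 4 * prof1$value, tolerance = 1e-8)
})

test_that("identical data at every slice gives a flat rate profile", {
  tr <- simulate_tree(32, seed = 8)
  x <- simulate_traits(tr, 0.5, cross_slice_corr = 0, seed = 8)$values[, 1]
  m <- matrix(x, 32, 5, dimnames = list(names(x), NULL))
  prof <- sigma2_profile(trait_profile(m, regions = rep("HW", 5)), tr,
                         model_policy = "BM")
  expect_equal(diff(range(prof$value)), 0)
})
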