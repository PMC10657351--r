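test_that("pure-birth trees are ultrametric with unit depth and seeded", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(tr$Nnode, 2)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(depths)), 1e-12)
  expect_equal(max(depths), 1, tolerance = 1e-12)

  big <- simulate_tree(50, seed = 2)
  expect_lt(diff(range(ape::node.depth.edgelength(big)[1:50])), 1e-12)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 7)),
                   ape::write.tree(simulate_tree(20, seed = 7)))
  expect_error(simulate_tree(2), "3 tips")
})

test_that("trait simulation honors rates, means and slice correlation", {
  tr <- simulate_tree(16, seed = 3)
  ## zero rate: every species sits exactly on the mean trend
  mu <- seq(1, 2, length.out = 5)
  pr0 <- simulate_traits(tr, rep(0, 5), mu = mu, regions = rep("HW", 5),
                         seed = 4)
  expect_equal(unname(pr0$values),
               matrix(mu, 16, 5, byrow = TRUE), tolerance = 1e-12)

  ## zero cross-slice correlation: whitened innovations uncorrelated
  big <- simulate_tree(24, seed = 18)
  C <- phylo_cov(big, "BM")
  U <- chol(C)
  pr <- simulate_traits(big, rep(1, 400), cross_slice_corr = 0,
                        regions = rep("HW", 400), seed = 18)
  eta <- backsolve(U, pr$values[rownames(C), ], transpose = TRUE)
  rho_adj <- cor(as.vector(eta[, -400]), as.vector(eta[, -1]))
  expect_lt(abs(rho_adj), 0.1)

  ## high correlation gives smooth profiles
  prs <- simulate_traits(big, rep(1, 400), cross_slice_corr = 0.9,
                         regions = rep("HW", 400), seed = 18)
  etas <- backsolve(U, prs$values[rownames(C), ], transpose = TRUE)
  rho_s <- cor(as.vector(etas[, -400]), as.vector(etas[, -1]))
  expect_gt(rho_s, 0.8)

  expect_error(simulate_traits(tr, rep(-1, 5)), "non-negative")
  expect_error(simulate_traits(tr, rep(1, 5), cross_slice_corr = 1), "corr")
})

test_that("trend-plus-noise null generator has no phylogenetic structure", {
  pr <- simulate_no_phylo_trend(20, "linear", noise_sd = 0.1, seed = 5)
  expect_equal(dim(pr$values), c(20L, 35L))
  truth <- attr(pr, "truth")$trend
  expect_lt(max(abs(colMeans(pr$values) - truth)), 0.1)
  expect_error(simulate_no_phylo_trend(20, "linear", noise_sd = 0),
               "degenerate")
  a <- simulate_no_phylo_trend(10, "logistic", noise_sd = 0.2, seed = 6)
  b <- simulate_no_phylo_trend(10, "logistic", noise_sd = 0.2, seed = 6)
  expect_identical(a$values, b$values)
})

test_that("parametric wings expose exact closed-form truth", {
  ## flat plate: zero camber height, camber trait = thickness / chord
  flat <- simulate_wing_pointcloud(camber_root = 0, camber_tip = 0,
                                   chord_root = 50, chord_tip = 50,
                                   thickness_root = 2, thickness_tip = 2,
                                   n_points = 20000, seed = 6)
  tt <- wing_truth_table(flat, slice_wing(flat))
  expect_equal(tt$camber, rep(2 / 50, nrow(tt)))
  tab <- measure_wing(flat, scale = FALSE)
  expect_lt(max(abs(tab$camber - 2 / 50) / (2 / 50)), 0.02)

  ## measurement error shrinks with point density (monotone on average
  ## over replicate clouds)
  errs <- vapply(c(6000, 24000, 96000), function(np) {
    mean(vapply(1:5, function(r) {
      sc <- simulate_wing_pointcloud(n_points = np, seed = 80 + r)
      tb <- measure_wing(sc, scale = FALSE)
      tr <- wing_truth_table(sc, slice_wing(sc))
      mean(abs(tb$xsa - tr$xsa) / tr$xsa, na.rm = TRUE)
    }, 0))
  }, 0)
  ## error decays to the discretization floor: non-increasing within noise,
  ## dense clouds well below the sparsest
  expect_true(all(diff(errs) < 1e-3))
  expect_lt(errs[3], errs[1] / 2)
})

test_that("study generation is complete, valid and byte-reproducible", {
  cfg <- synth_study_config(n_species = 24, n_specimens = 3, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st1 <- generate_study(cfg, d1)
  st2 <- generate_study(cfg, d2)
  expect_setequal(names(st1$profiles), c("camber", "chord", "xst", "xsa"))
  expect_equal(dim(st1$profiles$camber$values), c(24L, 36L))
  expect_true(all(st1$profiles$chord$values > 0))
  expect_setequal(unique(st1$clades), c("cladeA", "cladeB"))
  for (f in c("tree.nwk", "traits_camber.tsv", "clades.tsv", "manifest.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## round-trip through the TSV reader
  back <- read_trait_profile(file.path(d1, "traits_camber.tsv"))
  expect_equal(back$values, st1$profiles$camber$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(synth_study_config(n_species = 5), "floor")
})
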