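test_that("RDA is exact on noiseless piecewise-linear profiles", {
  pos <- (1:35)[-11]
  ## continuous line: no step
  y0 <- 2 + 0.5 * pos
  r0 <- suppressWarnings(rda(y0, positions = pos))
  expect_equal(r0$delta, 0, tolerance = 1e-10)
  expect_equal(r0$slope_below, 0.5, tolerance = 1e-10)
  expect_equal(r0$slope_above, 0.5, tolerance = 1e-10)

  ## intercept step of 3 at the cutoff
  y1 <- ifelse(pos >= 10.5, 5, 2) + 0.5 * pos
  r1 <- suppressWarnings(rda(y1, positions = pos))
  expect_equal(r1$delta, 3, tolerance = 1e-10)

  expect_error(rda(y1, positions = pos, cutoff = 50), "inside")
  expect_error(rda(y1[1:5], positions = pos[1:5], cutoff = 3.5), "3 points")
})

test_that("RDA delta is shift-invariant and scale-equivariant", {
  set.seed(2)
  pos <- (1:35)[-11]
  y <- 1 + 0.1 * pos + ifelse(pos >= 10.5, 0.8, 0) + rnorm(34, 0, 0.1)
  r <- rda(y, positions = pos)
  r_shift <- rda(y + 100, positions = pos)
  r_scale <- rda(3 * y, positions = pos)
  expect_equal(r_shift$delta, r$delta, tolerance = 1e-10)
  expect_equal(r_shift$p_delta, r$p_delta, tolerance = 1e-10)
  expect_equal(r_scale$delta, 3 * r$delta, tolerance = 1e-10)
})

test_that("RDA has power for a real step and nominal size without one", {
  set.seed(14)
  pos <- (1:35)[-11]
  hits <- deltas <- numeric(500)
  for (i in 1:500) {
    y <- 0.5 + 0.02 * pos + ifelse(pos >= 10.5, 1, 0) + rnorm(34, 0, 0.2)
    f <- rda(y, positions = pos)
    hits[i] <- f$p_delta < 0.05
    deltas[i] <- f$delta
  }
  expect_gt(mean(hits), 0.8)                  # 5-SD step: high power
  expect_gt(mean(deltas), 0.9)
  expect_lt(mean(deltas), 1.1)

  set.seed(15)
  false_pos <- mean(replicate(500, {
    y <- 0.5 + 0.02 * pos + rnorm(34, 0, 0.2)
    rda(y, positions = pos)$p_delta < 0.05
  }))
  expect_gte(false_pos, 0.01)
  expect_lte(false_pos, 0.10)
})

test_that("clade split recovers clade-specific rate scalars", {
  tr <- simulate_tree(96, seed = 15)
  clades <- wingevo:::synth_clades(tr, target_frac = 0.5)
  spA <- names(clades)[clades == "cladeA"]
  spB <- names(clades)[clades == "cladeB"]
  s2 <- rep(2e-3, 8)
  prA <- simulate_traits(prune_tree(tr, spA), s2, cross_slice_corr = 0.5,
                         regions = rep("HW", 8), seed = 151)
  prB <- simulate_traits(prune_tree(tr, spB), 2 * s2, cross_slice_corr = 0.5,
                         regions = rep("HW", 8), seed = 152)
  pr <- trait_profile(rbind(prA$values, prB$values),
                      regions = rep("HW", 8))
  res <- clade_split(pr, tr, clades, model_policy = "BM")
  ratio <- mean(res$cladeB$sigma2$value) / mean(res$cladeA$sigma2$value)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  expect_error(clade_split(pr, tr, clades[-1]), "missing")
})

test_that("rarefaction reduces to the full analysis at zero removals", {
  tr <- simulate_tree(24, seed = 16)
  pr <- simulate_traits(tr, rep(1e-3, 6), cross_slice_corr = 0.5,
                        regions = rep("HW", 6), seed = 16)
  full <- sigma2_profile(pr, tr, model_policy = "BM")
  sc <- rarefaction(pr, tr, removals = c(0, 10), n_reps = 4, seed = 16,
                    model_policy = "BM")
  expect_equal(sc$remove_0$sigma2$median, full$value, tolerance = 1e-10)
  expect_equal(unname(sc$remove_0$disparity$median),
               disparity_profile(pr)$value, tolerance = 1e-10)
  ## determinism
  sc2 <- rarefaction(pr, tr, removals = c(0, 10), n_reps = 4, seed = 16,
                     model_policy = "BM")
  expect_identical(sc$remove_10$sigma2$reps, sc2$remove_10$sigma2$reps)
  expect_error(rarefaction(pr, tr, removals = 20, n_reps = 2, seed = 1),
               "fewer than")
})

test_that("posterior tree scan summarizes rate uncertainty", {
  tr <- simulate_tree(32, seed = 17)
  pr <- simulate_traits(tr, rep(5e-4, 5), cross_slice_corr = 0.5,
                        regions = rep("HW", 5), seed = 17)
  ## identical trees: MAD is exactly zero
  scan0 <- posterior_tree_scan(pr, rep(list(tr), 10), model_policy = "BM")
  expect_equal(scan0$mad, rep(0, 5))
  expect_equal(scan0$n_trees_used, 10)

  ## jittered branch lengths: median rate near the generating rate
  big <- simulate_tree(128, seed = 18)
  prb <- simulate_traits(big, rep(5e-4, 10), cross_slice_corr = 0,
                         regions = rep("HW", 10), seed = 18)
  set.seed(17)
  trees <- lapply(1:50, function(i) {
    t2 <- big
    t2$edge.length <- t2$edge.length * exp(rnorm(length(t2$edge.length),
                                                 0, 0.05))
    t2
  })
  scan <- posterior_tree_scan(prb, trees, model_policy = "BM")
  expect_lt(abs(mean(scan$median) - 5e-4) / 5e-4, 0.10)
  expect_lt(max(abs(scan$median - 5e-4) / 5e-4), 0.40)

  ## disparity is tree-free by definition
  d1 <- disparity_profile(pr)$value
  expect_identical(d1, disparity_profile(pr)$value)
})
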