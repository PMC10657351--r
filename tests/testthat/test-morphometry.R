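test_that("alignment recovers the measurement frame from rigid motions", {
  ## axis-aligned tapered box-like cloud already in convention
  set.seed(1)
  n <- 5000
  x <- runif(n, 0, 100)
  y <- runif(n, -1, 1) * (20 - 0.1 * x)          # taper: tip at large x
  z <- 0.5 * (1 - (y / (20 - 0.1 * x))^2) + runif(n, 0, 0.05)
  P <- cbind(x, y, z)
  A0 <- align_pointcloud(P)
  ## principal frame of an already-aligned cloud: axes unchanged up to sign
  expect_lt(max(abs(abs(attr(A0, "rotation")) - diag(3))), 0.05)

  ## 90-degree rotation about Z is undone exactly (rigid, no scaling)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  A1 <- align_pointcloud(P %*% Rz)
  expect_lt(max(abs(A1 - A0)), 1e-9)

  ## random rigid motion: all four traits invariant
  th <- c(0.4, 1.1, 2.2)
  R1 <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  R2 <- matrix(c(cos(th[3]), sin(th[3]), 0,
                 -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  Pm <- sweep(P %*% (R1 %*% R2), 2, c(17, -4, 8), "+")
  A2 <- align_pointcloud(Pm)
  expect_lt(max(abs(A2 - A0)), 1e-6)

  expect_error(align_pointcloud(cbind(1:10, 2 * (1:10), 3 * (1:10))),
               "degenerate")
})

test_that("rotated synthetic wings give the same slice measurements", {
  scan <- simulate_wing_pointcloud(n_points = 21000, seed = 1)
  base <- scan
  base$points <- align_pointcloud(scan$points)
  base$wrist_x <- min(base$points[, 1]) +
    (scan$wrist_x - min(scan$points[, 1]))
  tab0 <- measure_wing(base, scale = FALSE)
  set.seed(1)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0,
                 -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  rot <- scan
  rot$points <- sweep(scan$points %*% (Rx %*% Rz), 2, c(5, 9, -2), "+")
  rot$points <- align_pointcloud(rot$points)
  rot$wrist_x <- min(rot$points[, 1]) +
    (scan$wrist_x - min(scan$points[, 1]))
  tab1 <- measure_wing(rot, scale = FALSE)
  expect_lt(max(abs(tab1$chord - tab0$chord) / tab0$chord), 0.01)
  expect_lt(max(abs(tab1$camber - tab0$camber) / tab0$camber), 0.01)
})

test_that("slice arithmetic follows the wrist-to-tip convention", {
  set.seed(2)
  mk_scan <- function(xmin, wrist, xmax) {
    x <- c(xmin, xmax, runif(30000, xmin, xmax))   # exact spanwise extremes
    wing_scan(cbind(x, runif(30002, 0, 40), runif(30002, 0, 2)),
              "flat", 100, wrist)
  }
  s1 <- slice_wing(mk_scan(0, 100, 350))
  expect_equal(attr(s1, "width"), 10)
  expect_equal(attr(s1, "n_aw"), 10)
  expect_equal(sum(vapply(s1, `[[`, "", "region") == "HW"), 25L)
  expect_equal(sum(vapply(s1, `[[`, "", "region") == "WRIST"), 1L)
  expect_equal(length(s1), 35L)

  s2 <- slice_wing(mk_scan(0, 325, 350))
  expect_equal(attr(s2, "width"), 1)
  expect_equal(sum(vapply(s2, `[[`, "", "region") == "HW"), 25L)

  ## armwing bin count from the generator geometry (oracle: direct count)
  scan <- simulate_wing_pointcloud(span = 300, aw_frac = 0.3,
                                   n_points = 30000, seed = 2)
  s3 <- slice_wing(scan)
  w <- (300 - 0.3 * 300) / 25
  expect_equal(attr(s3, "n_aw"), floor(0.3 * 300 / w))

  bad <- mk_scan(0, 100, 350); bad$wrist_x <- 351
  expect_error(slice_wing(bad), "extent")
})

test_that("slice traits match closed forms on simple sections", {
  ## rectangle: chord 40, thickness 2, camber 0.05, area 80
  m <- measure_slice(rect_slice(), surface = "solid")
  expect_equal(m$chord, 40, tolerance = 0.02)
  ## slice-global extent is exact here; the station-wise maximum carries a
  ## small max-order-statistic inflation on solid fills
  expect_equal(measure_slice(rect_slice(), surface = "solid",
                             xst_mode = "global")$xst, 2, tolerance = 0.02)
  expect_equal(m$xst, 2, tolerance = 0.05)
  expect_equal(m$camber, 0.05, tolerance = 0.02)
  expect_equal(m$xsa, 80, tolerance = 0.02)

  ## circular-arc plate, zero shell thickness: camber = rise / chord
  set.seed(6)
  y <- runif(5000, -20, 20)
  z <- 4 * (1 - (y / 20)^2)
  arc <- cbind(runif(5000, 0, 5), y, z)
  expect_equal(measure_slice(arc)$camber, 0.1, tolerance = 0.02)

  ## random convex polygon: area within 2% of the shoelace value
  set.seed(3)
  ang <- sort(runif(8, 0, 2 * pi))
  vx <- 3 * cos(ang); vy <- 2 * sin(ang)
  shoe <- 0.5 * abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy))
  N <- 40000
  px <- runif(N, -3, 3); py <- runif(N, -2, 2)
  inside <- rep(FALSE, N); j <- length(vx)
  for (i in seq_along(vx)) {
    f <- (vy[i] > py) != (vy[j] > py)
    xi <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside[f & px < xi] <- !inside[f & px < xi]
    j <- i
  }
  poly <- cbind(0.5, px[inside], py[inside])
  expect_equal(measure_slice(poly, surface = "solid")$xsa, shoe,
               tolerance = 0.02)

  expect_error(measure_slice(rect_slice(n = 5)), "10 points")
})

test_that("mass scaling uses the allometric exponents and round-trips", {
  tr <- structure(list(camber = 0.08, chord = 20, xst = 3, xsa = 50,
                       scaled = FALSE), class = "slice_traits")
  sc <- scale_by_mass(tr, 1000)
  expect_equal(sc$chord, 2)
  expect_equal(sc$xsa, 0.5)
  expect_equal(sc$camber, 0.08)
  back <- unscale_by_mass(sc, 1000)
  expect_equal(back[c("camber", "chord", "xst", "xsa")],
               tr[c("camber", "chord", "xst", "xsa")])
  expect_error(scale_by_mass(tr, -5), "body_mass")
})

test_that("coordinate scaling propagates covariantly to the traits", {
  scan <- simulate_wing_pointcloud(n_points = 15000, seed = 4)
  sl <- slice_wing(scan)
  pts <- sl[[20]]$points
  m1 <- measure_slice(pts)
  m2 <- measure_slice(pts * 2.5)
  expect_equal(m2$chord, 2.5 * m1$chord, tolerance = 1e-10)
  expect_equal(m2$xst, 2.5 * m1$xst, tolerance = 1e-10)
  expect_equal(m2$xsa, 2.5^2 * m1$xsa, tolerance = 1e-10)
  expect_equal(m2$camber, m1$camber, tolerance = 1e-10)
})

test_that("species summaries take slice-wise medians over specimens", {
  mk_tab <- function(vals, sp) {
    structure(data.frame(slice_index = 1:36,
                         region = c(rep("AW", 10), "WRIST", rep("HW", 25)),
                         camber = vals, chord = vals + 1, xst = vals + 2,
                         xsa = vals + 3, n_points = 100),
              species_id = sp)
  }
  ## single specimen: medians equal that specimen
  one <- summarize_species(list(mk_tab(rep(0.5, 36), "sp1")))
  expect_equal(unname(one$camber$values[1, ]), rep(0.5, 36))

  ## odd-n median
  three <- summarize_species(list(mk_tab(rep(1, 36), "sp1"),
                                  mk_tab(rep(2, 36), "sp1"),
                                  mk_tab(rep(10, 36), "sp1")))
  expect_equal(unname(three$camber$values[1, ]), rep(2, 36))

  ## known-noise cohort: median within the noise MAD of the truth
  set.seed(4)
  truth <- seq(2, 1, length.out = 36)
  tabs <- lapply(1:6, function(i)
    mk_tab(truth + rnorm(36, 0, 0.05), "spX"))
  med <- summarize_species(tabs)
  expect_lt(max(abs(med$camber$values[1, ] - truth)), 3 * 0.05)
})

test_that("standardization handles wrist policy, log10 and truncation", {
  set.seed(7)
  m <- matrix(runif(8 * 36, 1, 2), 8, 36,
              dimnames = list(sprintf("s%d", 1:8), NULL))
  pr <- trait_profile(m)
  std <- standardize_profiles(pr)
  expect_equal(ncol(std$values), 35)
  expect_false("WRIST" %in% std$regions)

  ones <- trait_profile(matrix(1, 4, 35,
                               dimnames = list(letters[1:4], NULL)))
  lg <- standardize_profiles(ones, log10 = TRUE)
  expect_true(all(lg$values == 0))

  ## species with missing slices are dropped with a message
  m2 <- m; m2[2, 5] <- NA
  expect_message(std2 <- standardize_profiles(trait_profile(m2)), "excluding")
  expect_equal(nrow(std2$values), 7)
})

test_that("measured traits recover analytic truth on parametric wings", {
  ## ~500 points per slice
  scan <- simulate_wing_pointcloud(n_points = 21000, seed = 20)
  tab <- measure_wing(scan, scale = FALSE)
  tt <- wing_truth_table(scan, slice_wing(scan))
  rel <- function(a, b) max(abs(a - b) / b, na.rm = TRUE)
  expect_lt(rel(tab$chord, tt$chord), 0.02)
  expect_lt(rel(tab$camber, tt$camber), 0.02)
  expect_lt(rel(tab$xst, tt$xst), 0.02)
  expect_lt(rel(tab$xsa, tt$xsa), 0.05)
})
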