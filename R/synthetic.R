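#' Simulate an ultrametric pure-birth tree
#'
#' A Yule (pure-birth) tree rescaled to unit root-to-tip depth, the default
#' stand-in tree source for synthetic studies.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param seed Integer seed.
#' @return An ultrametric `"phylo"` with tip labels `sp001, sp002, ...` and
#'   depth 1.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 3) stop("need at least 3 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  h <- node_heights(tr)
  depth <- max(h[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tr
}

#' Simulate trait profiles with controlled evolutionary structure
#'
#' Generates a species x slice trait matrix on a phylogeny: at slice s, tip
#' values are multivariate normal with mean `mu[s] * 1` and covariance
#' `sigma2[s] * C`, where C is the BM (or OU) covariance of the tree.
#' Innovations share an AR(1) correlation `cross_slice_corr` between
#' adjacent slices, so profiles are spanwise-smooth while each slice keeps
#' its marginal rate exactly.
#'
#' @param tree A `"phylo"`.
#' @param sigma2 Numeric vector of per-slice rates (the spanwise rate
#'   profile; stored as ground truth).
#' @param model `"BM"` or `"OU"`.
#' @param alpha OU pull (ignored for BM).
#' @param mu Per-slice mean trend (default 0).
#' @param cross_slice_corr AR(1) correlation of innovations between adjacent
#'   slices, in `[0, 1)`.
#' @param regions Region labels per slice (defaulted from the slice count).
#' @param trait Trait name for the returned profile.
#' @param seed Integer seed.
#' @return A `"trait_profile"` with attribute `"truth"`: a list holding the
#'   generating `sigma2`, `mu`, `model`, `alpha`, `cross_slice_corr`.
#' @export
simulate_traits <- function(tree, sigma2, model = c("BM", "OU"), alpha = 0,
                            mu = 0, cross_slice_corr = 0.8, regions = NULL,
                            trait = "synthetic", seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  p <- length(sigma2)
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  if (cross_slice_corr < 0 || cross_slice_corr >= 1)
    stop("cross_slice_corr must be in [0, 1)")
  mu <- rep_len(mu, p)
  n <- length(tree$tip.label)
  V <- phylo_cov(tree, model, sigma2 = 1, alpha = alpha)
  U <- tryCatch(chol(V), error = function(e)
    stop("non-positive-definite covariance for the requested model"))
  rho <- cross_slice_corr
  ## AR(1) innovations in the phylo-whitened space
  eta <- matrix(stats::rnorm(n * p), n, p)
  eps <- matrix(0, n, p)
  eps[, 1] <- eta[, 1]
  if (p > 1) for (s in 2:p)
    eps[, s] <- rho * eps[, s - 1] + sqrt(1 - rho^2) * eta[, s]
  X <- crossprod(U, eps)                      # n x p, each column ~ MVN(0, V)
  X <- sweep(X, 2, sqrt(sigma2), "*")
  X <- sweep(X, 2, mu, "+")
  rownames(X) <- rownames(V)
  if (is.null(regions))
    regions <- if (p %in% c(35L, 36L)) default_regions(p) else rep("HW", p)
  pr <- trait_profile(X, trait = trait, regions = regions)
  attr(pr, "truth") <- list(sigma2 = sigma2, mu = mu, model = model,
                            alpha = alpha, cross_slice_corr = rho)
  pr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate trend-plus-noise trait data with no phylogenetic structure
#'
#' Species x slice values are a shared spanwise trend `f(s)` plus iid
#' Gaussian noise; no tree is involved. This is the null generator for the
#' trend-bias check of the covariance-ratio test.
#'
#' @param n_species Number of species rows.
#' @param trend `"linear"`, `"exponential"` or `"logistic"` (all decreasing
#'   base to tip, mimicking the observed spanwise trait trends), or a numeric
#'   vector of length `n_slices`.
#' @param noise_sd Standard deviation of the iid noise (> 0).
#' @param n_slices Number of slices (default 35).
#' @param base,tip Trend endpoints for the named shapes.
#' @param seed Integer seed.
#' @return A `"trait_profile"` with attribute `"truth"` (the trend vector).
#' @export
simulate_no_phylo_trend <- function(n_species, trend = "linear", noise_sd,
                                    n_slices = 35L, base = 1, tip = 0.2,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd <= 0) stop("degenerate: noise_sd must be > 0 (zero noise makes all species identical)")
  s <- seq(0, 1, length.out = n_slices)
  f <- if (is.numeric(trend)) {
    if (length(trend) != n_slices) stop("numeric trend must have n_slices values")
    trend
  } else switch(match.arg(trend, c("linear", "exponential", "logistic")),
    linear = base + (tip - base) * s,
    exponential = tip + (base - tip) * exp(-3 * s) / 1,
    logistic = tip + (base - tip) / (1 + exp(10 * (s - 0.5)))
  )
  X <- matrix(rep(f, each = n_species), n_species, n_slices) +
    matrix(stats::rnorm(n_species * n_slices, sd = noise_sd), n_species)
  rownames(X) <- sprintf("sp%03d", seq_len(n_species))
  pr <- trait_profile(X, trait = "trend_null",
                      regions = default_regions(n_slices))
  attr(pr, "truth") <- list(trend = f, noise_sd = noise_sd)
  pr
}

#' Simulate a parametric 3D wing point cloud with analytic ground truth
#'
#' Samples points on a parametric wing surface: linearly tapered chord
#' `c(x)`, circular-arc (parabolic) camber of height `h(x)` and a thin shell
#' of vertical thickness `t(x)`; half of the points lie on the lower surface
#' `z = a(y)` and half on the upper surface `z = a(y) + t(x)`, with
#' `a(y) = h(x) (1 - (2y/c)^2)`. The generating functions give exact
#' per-slice trait values: `chord = c(x)`, `xst = t(x)`,
#' `camber = (h + t)/c`, `xsa = c t`.
#'
#' @param span Wing length (mm), base at x = 0.
#' @param aw_frac Armwing fraction of the span; the wrist sits at
#'   `aw_frac * span`.
#' @param chord_root,chord_tip Chord at base and tip (mm).
#' @param camber_root,camber_tip Camber-height-to-chord ratio at base/tip.
#' @param thickness_root,thickness_tip Shell thickness at base/tip (mm).
#' @param n_points Total number of surface points.
#' @param body_mass Body mass (g) attached to the scan.
#' @param species_id,specimen_id Labels for the scan.
#' @param seed Integer seed.
#' @return A `"wing_scan"` with attribute `"truth"`: a function
#'   `truth(x)` returning a data.frame of the analytic `chord`, `xst`,
#'   `camber`, `xsa` at spanwise positions `x`.
#' @export
simulate_wing_pointcloud <- function(span = 350, aw_frac = 0.4,
                                     chord_root = 80, chord_tip = 40,
                                     camber_root = 0.10, camber_tip = 0.05,
                                     thickness_root = 4, thickness_tip = 1.5,
                                     n_points = 40000L, body_mass = 300,
                                     species_id = "synthetic",
                                     specimen_id = "synthetic-1",
                                     seed = NULL) {
  if (span <= 0) stop("span must be > 0")
  if (chord_root <= 0 || chord_tip <= 0) stop("chord must be > 0")
  if (!is.null(seed)) set.seed(seed)
  lin <- function(a, b) function(x) a + (b - a) * x / span
  cfun <- lin(chord_root, chord_tip)
  hfun <- function(x) lin(camber_root, camber_tip)(x) * cfun(x)
  tfun <- lin(thickness_root, thickness_tip)
  x <- stats::runif(n_points, 0, span)
  cx <- cfun(x)
  y <- stats::runif(n_points, -cx / 2, cx / 2)
  a <- hfun(x) * (1 - (2 * y / cx)^2)
  upper <- stats::runif(n_points) < 0.5
  z <- a + ifelse(upper, tfun(x), 0)
  scan <- wing_scan(cbind(x, y, z), species_id = species_id,
                    body_mass = body_mass, wrist_x = aw_frac * span,
                    specimen_id = specimen_id)
  attr(scan, "truth") <- function(xq) {
    data.frame(x = xq, chord = cfun(xq), xst = tfun(xq),
               camber = (hfun(xq) + tfun(xq)) / cfun(xq),
               xsa = cfun(xq) * tfun(xq))
  }
  ## per-slab truth for a slice bin [x0, x1]: chord is the slab-midpoint
  ## (= slab-mean, c linear) value, where the edge-attainment bias and the
  ## sampling deficit of the Y-range estimator offset; camber's numerator
  ## and denominator extremes are both attained at the proximal edge for
  ## base-to-tip tapering wings, so its truth is the edge supremum ratio;
  ## xst and xsa are slab averages (linear c, t -> exact)
  attr(scan, "truth_slab") <- function(x0, x1) {
    xc <- (x0 + x1) / 2
    data.frame(x0 = x0, x1 = x1,
               chord = cfun(xc),
               camber = (hfun(x0) + tfun(x0)) / cfun(x0),
               xst = tfun(xc),
               xsa = cfun(xc) * tfun(xc) +
                 (cfun(x1) - cfun(x0)) * (tfun(x1) - tfun(x0)) / 12)
  }
  scan
}

#' Analytic per-slice truth table for a synthetic wing scan
#'
#' Evaluates the generating functions of a [simulate_wing_pointcloud()] scan
#' over the slice bins that [slice_wing()] produces, so measured traits can
#' be compared against exact ground truth bin by bin.
#'
#' @param scan A `"wing_scan"` carrying a `"truth_slab"` attribute.
#' @param slices The `"wing_slices"` from [slice_wing()] on the same scan.
#' @return A data.frame with one row per slice: `slice_index`, `region`,
#'   `chord`, `camber`, `xst`, `xsa`.
#' @export
wing_truth_table <- function(scan, slices) {
  ts <- attr(scan, "truth_slab")
  if (is.null(ts)) stop("scan carries no analytic truth")
  w <- attr(slices, "width")
  n_aw <- attr(slices, "n_aw")
  xmin <- scan$wrist_x - n_aw * w
  x0 <- xmin + (seq_along(slices) - 1L) * w
  tt <- ts(x0, x0 + w)
  data.frame(slice_index = seq_along(slices),
             region = vapply(slices, `[[`, "", "region"),
             chord = tt$chord, camber = tt$camber, xst = tt$xst,
             xsa = tt$xsa)
}

#' Default configuration of a synthetic study
#'
#' The defaults emulate the design of the empirical study the pipeline is
#' built for: 178 species (6 specimens each), an ultrametric unit-depth
#' tree, 10 armwing + 1 wrist + 25 handwing slices, four traits with smooth
#' decreasing base-to-tip mean trends on the scale of mass-scaled bird wing
#' measurements, and a spanwise evolutionary-rate profile that rises
#' quadratically toward the wingtip (the mechanical-sensitivity gradient),
#' with an optional step at the wrist.
#'
#' @param n_species Number of species.
#' @param n_specimens Specimens per species (median-summarized).
#' @param n_aw,n_hw Armwing / handwing slice counts (wrist bin added).
#' @param birth_rate Tree simulation rate.
#' @param model Evolutionary model for trait simulation (`"BM"` or `"OU"`).
#' @param alpha OU pull (per unit depth).
#' @param cross_slice_corr AR(1) innovation correlation between slices.
#' @param sigma2_base,sigma2_tip Rate at the wing base and tip; the profile
#'   is `base + (tip - base) * pos^2` with `pos` in `[0, 1]`.
#' @param wrist_step Multiplier applied to handwing rates (1 = pure
#'   gradient; > 1 injects a modular step).
#' @param measurement_sd Specimen-level iid measurement noise, as a fraction
#'   of each trait's mean-trend range.
#' @param seed Master seed.
#' @return A list of class `"synth_study_config"`.
#' @export
synth_study_config <- function(n_species = 178L, n_specimens = 6L,
                               n_aw = 10L, n_hw = 25L, birth_rate = 1,
                               model = "BM", alpha = 0,
                               cross_slice_corr = 0.8,
                               sigma2_base = 2e-4, sigma2_tip = 1.2e-3,
                               wrist_step = 1, measurement_sd = 0.02,
                               seed = 1L) {
  if (n_species < 6) stop("n_species below the rarefaction floor of 6")
  cfg <- list(n_species = n_species, n_specimens = n_specimens, n_aw = n_aw,
              n_hw = n_hw, birth_rate = birth_rate, model = model,
              alpha = alpha, cross_slice_corr = cross_slice_corr,
              sigma2_base = sigma2_base, sigma2_tip = sigma2_tip,
              wrist_step = wrist_step, measurement_sd = measurement_sd,
              seed = as.integer(seed))
  class(cfg) <- "synth_study_config"
  cfg
}

## Mean spanwise trends per trait (base -> tip), on the scale of mass-scaled
## measurements from real spread wings.
synth_mean_trends <- function(p) {
  s <- seq(0, 1, length.out = p)
  list(camber = 0.11 - 0.04 * s,
       chord = 20.4 - 7.2 * s,
       xst = 2.1 - 1.6 * s,
       xsa = 17.2 - 15.1 * s)
}

#' Generate a complete synthetic study
#'
#' Simulates a tree, the four species-median trait profiles (with
#' specimen-level measurement noise median-summarized away, as in the
#' measurement pipeline), and a two-clade labeling; optionally writes
#' everything to disk in the formats the readers consume.
#'
#' @param config A [synth_study_config()].
#' @param dir Optional output directory; when given, writes `tree.nwk`,
#'   `traits_<trait>.tsv` (+ `.meta`), `clades.tsv` and `manifest.tsv`.
#' @return A list: `tree`, `profiles` (named list of `"trait_profile"`s,
#'   each with its generating truth attached), `clades` (named vector),
#'   `config`.
#' @export
generate_study <- function(config = synth_study_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_study_config"))
  set.seed(config$seed)
  p <- config$n_aw + 1L + config$n_hw
  tree <- simulate_tree(config$n_species, config$birth_rate)
  pos <- seq(0, 1, length.out = p)
  s2 <- config$sigma2_base + (config$sigma2_tip - config$sigma2_base) * pos^2
  hw <- default_regions(p) == "HW"
  s2[hw] <- s2[hw] * config$wrist_step
  trends <- synth_mean_trends(p)
  ## per-trait rate scaling so sigma2 is on each trait's own scale
  scale2 <- vapply(trends, function(f) (max(f) / max(trends$camber))^2, 0)
  profiles <- lapply(names(trends), function(tr) {
    pr <- simulate_traits(tree, sigma2 = s2 * scale2[[tr]],
                          model = config$model, alpha = config$alpha,
                          mu = trends[[tr]],
                          cross_slice_corr = config$cross_slice_corr,
                          trait = tr)
    ## specimen-level measurement noise, median over specimens
    if (config$n_specimens > 1 && config$measurement_sd > 0) {
      sdv <- config$measurement_sd * diff(range(trends[[tr]]))
      n <- nrow(pr$values)
      meds <- array(stats::rnorm(n * p * config$n_specimens, sd = sdv),
                    c(n, p, config$n_specimens))
      pr$values <- pr$values + apply(meds, c(1, 2), stats::median)
    }
    pr$values <- pmax(pr$values, 1e-4)       # traits are physically positive
    pr
  })
  names(profiles) <- names(trends)
  clades <- synth_clades(tree)
  out <- list(tree = tree, profiles = profiles, clades = clades,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    for (tr in names(profiles))
      write_trait_profile(profiles[[tr]],
                          file.path(dir, paste0("traits_", tr, ".tsv")))
    utils::write.table(
      data.frame(species = names(clades), clade = unname(clades)),
      file.path(dir, "clades.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(key = c("n_species", "n_specimens", "seed", "model"),
                 value = c(config$n_species, config$n_specimens, config$seed,
                           config$model)),
      file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  out
}

## Two-clade labeling: the clade whose tip count is closest to ~63% of the
## sample (the passerine share of the empirical design) vs everything else.
synth_clades <- function(tree, target_frac = 113 / 178) {
  n <- length(tree$tip.label)
  target <- target_frac * n
  best <- NULL; bestd <- Inf
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- tips_under(tree, node)
    d <- abs(length(tips) - target)
    if (d < bestd && length(tips) < n) { best <- tips; bestd <- d }
  }
  cl <- stats::setNames(rep("cladeB", n), tree$tip.label)
  cl[best] <- "cladeA"
  cl
}

tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}
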