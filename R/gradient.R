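#' Regression-discontinuity analysis of a spanwise profile
#'
#' Tests for an intercept step in a spanwise statistic (sigma^2, disparity,
#' ...) at a pre-assigned cutoff, here the wrist joint. Fits the global
#' two-segment linear model
#' `y = b0 + b1 (x - c) + delta D + b2 D (x - c)`, `D = 1[x >= c]`,
#' by ordinary least squares; `delta` is the intercept discontinuity at the
#' cutoff and its two-sided t-test p-value is the headline RDA p. Any wrist
#' slice is excluded from both sides.
#'
#' @param profile A `"span_profile"` data.frame (columns `slice`, `region`,
#'   `value`), or a numeric vector of values with `positions`.
#' @param cutoff Cutoff position on the slice axis; default 10.5, between
#'   armwing slice 10 and handwing slice 1 of the standard 35-slice layout.
#' @param positions Positions for a bare numeric `profile`.
#' @return A list of class `"rda_result"`: `delta`, `p_delta`,
#'   `slope_below`, `slope_above`, `slope_change`, `p_slope_change`,
#'   `cutoff`, `n_below`, `n_above`, and the fitted `lm` object.
#' @export
rda <- function(profile, cutoff = 10.5, positions = NULL) {
  if (inherits(profile, "data.frame")) {
    keep <- profile$region != "WRIST" & !is.na(profile$value)
    x <- profile$slice[keep]
    y <- profile$value[keep]
  } else {
    if (is.null(positions)) positions <- seq_along(profile)
    keep <- !is.na(profile)
    x <- positions[keep]; y <- profile[keep]
  }
  if (cutoff <= min(x) || cutoff >= max(x)) stop("cutoff must be strictly inside the profile range")
  D <- as.numeric(x >= cutoff)
  if (sum(D == 0) < 3 || sum(D == 1) < 3)
    stop("need at least 3 points on each side of the cutoff")
  xc <- x - cutoff
  fit <- stats::lm(y ~ xc + D + D:xc)
  cf <- summary(fit)$coefficients
  ## noiseless piecewise-linear inputs: p undefined (0 residual); report 0/NA
  get <- function(nm, col) if (nm %in% rownames(cf)) cf[nm, col] else NA_real_
  structure(list(
    delta = get("D", 1), p_delta = get("D", 4),
    slope_below = get("xc", 1),
    slope_above = get("xc", 1) + get("xc:D", 1),
    slope_change = get("xc:D", 1), p_slope_change = get("xc:D", 4),
    cutoff = cutoff, n_below = sum(D == 0), n_above = sum(D == 1),
    fit = fit), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("regression discontinuity at cutoff %.2f: delta = %.6g (p = %.4g)\n",
              x$cutoff, x$delta, x$p_delta))
  cat(sprintf("  slopes: %.6g (below) vs %.6g (above); n = %d | %d\n",
              x$slope_below, x$slope_above, x$n_below, x$n_above))
  invisible(x)
}

#' Per-clade rate and disparity profiles
#'
#' Splits the species into labeled clades (e.g. passerines vs
#' non-passerines), prunes the tree to each subset and recomputes the
#' sigma^2 and disparity profiles per clade.
#'
#' @param profile A `"trait_profile"`.
#' @param tree A `"phylo"` containing all species.
#' @param clades Named character vector or factor: clade label per species
#'   (names = species ids), covering all profile species.
#' @param metric Disparity metric, see [disparity_profile()].
#' @param model_policy See [sigma2_profile()].
#' @return A named list per clade, each with `sigma2` and `disparity`
#'   span profiles and `n_species`.
#' @export
clade_split <- function(profile, tree, clades, metric = "variance",
                        model_policy = "best_aicc") {
  sp <- rownames(profile$values)
  if (!all(sp %in% names(clades)))
    stop("clade labels missing for some species")
  cl <- clades[sp]
  out <- lapply(split(sp, cl), function(members) {
    if (!length(members)) stop("empty clade")
    if (length(members) < 10)
      warning("clade with fewer than 10 species: ", length(members))
    sub <- profile
    sub$values <- profile$values[members, , drop = FALSE]
    list(sigma2 = sigma2_profile(sub, prune_tree(tree, members),
                                 model_policy = model_policy),
         disparity = disparity_profile(sub, metric = metric),
         n_species = length(members))
  })
  out
}

#' Taxon rarefaction of rate and disparity profiles
#'
#' Repeatedly removes a given number of taxa at random (with replacement of
#' the removed taxa between draws), recomputes the sigma^2 and disparity
#' profiles on the retained species, and summarizes each slice by the median
#' and median absolute deviation (MAD) over replicates.
#'
#' @param profile A `"trait_profile"`.
#' @param tree A `"phylo"`.
#' @param removals Integer vector of how many taxa to remove per scan point.
#' @param n_reps Replicates per removal count.
#' @param seed Integer seed.
#' @param statistic `"sigma2"`, `"disparity"`, or both (default).
#' @param model_policy See [sigma2_profile()]; `"BM"` is markedly faster for
#'   large scans.
#' @param metric Disparity metric.
#' @return A list of class `"robustness_scan"`: per removal count, per
#'   statistic, a list with `median` and `mad` per slice (and the replicate
#'   matrix `reps`).
#' @export
rarefaction <- function(profile, tree, removals, n_reps = 10L, seed = NULL,
                        statistic = c("sigma2", "disparity"),
                        model_policy = "best_aicc", metric = "variance") {
  statistic <- match.arg(statistic, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sp <- rownames(profile$values)
  n <- length(sp)
  if (any(n - removals < 3)) stop("removal would leave fewer than 3 species")
  if (any(n - removals < 6)) stop("removal would leave fewer than 6 species")
  out <- lapply(removals, function(k) {
    reps <- lapply(seq_len(if (k == 0) 1L else n_reps), function(i) {
      keep <- if (k == 0) sp else sample(sp, n - k)
      sub <- profile
      sub$values <- profile$values[keep, , drop = FALSE]
      r <- list()
      if ("sigma2" %in% statistic)
        r$sigma2 <- sigma2_profile(sub, prune_tree(tree, keep),
                                   model_policy = model_policy)$value
      if ("disparity" %in% statistic)
        r$disparity <- disparity_profile(sub, metric = metric)$value
      r
    })
    lapply(stats::setNames(statistic, statistic), function(st) {
      m <- do.call(rbind, lapply(reps, `[[`, st))
      list(median = apply(m, 2, stats::median),
           mad = apply(m, 2, stats::mad),
           reps = m)
    })
  })
  names(out) <- paste0("remove_", removals)
  structure(out, class = "robustness_scan", removals = removals)
}

#' Rate profiles across a set of candidate trees
#'
#' Recomputes a spanwise statistic profile for every tree in a posterior (or
#' otherwise uncertain) tree set and summarizes per slice by median and MAD.
#' Disparity does not depend on the tree, so only tree-dependent statistics
#' (sigma^2) are recomputed.
#'
#' @param profile A `"trait_profile"`.
#' @param trees A list of `"phylo"` objects (e.g. from [read_tree_set()]).
#' @param statistic Currently `"sigma2"`.
#' @param model_policy See [sigma2_profile()].
#' @return A list of class `"robustness_scan"` with `median`, `mad` per
#'   slice, the replicate matrix `reps`, and `n_trees_used`.
#' @export
posterior_tree_scan <- function(profile, trees, statistic = "sigma2",
                                model_policy = "best_aicc") {
  statistic <- match.arg(statistic)
  sp <- rownames(profile$values)
  reps <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!all(sp %in% tr$tip.label)) {
      message("tree ", i, " skipped: missing taxa")
      next
    }
    reps[[length(reps) + 1L]] <-
      sigma2_profile(profile, tr, model_policy = model_policy)$value
  }
  if (!length(reps)) stop("no usable trees")
  m <- do.call(rbind, reps)
  structure(list(median = apply(m, 2, stats::median),
                 mad = apply(m, 2, stats::mad),
                 reps = m, n_trees_used = nrow(m)),
            class = "robustness_scan")
}
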