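#' Construct a wing scan object
#'
#' A single specimen's aligned (or to-be-aligned) 3D wing point cloud plus
#' the metadata the slicing pipeline needs.
#'
#' @param points Numeric n x 3 matrix of coordinates (mm); columns X
#'   (spanwise, base to tip), Y (chordwise, leading to trailing edge), Z
#'   (thickness, ventral to dorsal).
#' @param species_id Taxon label.
#' @param body_mass Body mass in grams (> 0).
#' @param wrist_x Spanwise coordinate of the wrist joint, in the aligned
#'   frame (mm). Required per-scan metadata; wing thickness tapers smoothly
#'   through the wrist so no landmark-free detector is attempted.
#' @param specimen_id,side Optional provenance labels.
#' @return An object of class `"wing_scan"`.
#' @export
wing_scan <- function(points, species_id, body_mass, wrist_x,
                      specimen_id = NA_character_, side = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 3) stop("points must be an n x 3 matrix, n >= 3")
  if (!is.finite(body_mass) || body_mass <= 0) stop("body_mass must be > 0")
  if (qr(sweep(points, 2, colMeans(points)))$rank < 2)
    stop("degenerate point cloud: points are collinear")
  ## wrist_x is given in the aligned frame, so its position within the
  ## spanwise extent is validated at slicing time, after alignment
  structure(list(points = unname(points), species_id = species_id,
                 body_mass = body_mass, wrist_x = wrist_x,
                 specimen_id = specimen_id, side = side),
            class = "wing_scan")
}

#' @export
print.wing_scan <- function(x, ...) {
  r <- max(x$points[, 1]) - min(x$points[, 1])
  cat(sprintf("wing_scan: %s (%s), %d points, wing length %.1f mm, mass %.1f g, wrist at %.1f mm\n",
              x$species_id, x$specimen_id, nrow(x$points), r, x$body_mass, x$wrist_x))
  invisible(x)
}

#' Align a wing point cloud to the standard measurement frame
#'
#' Rigidly rotates (and centers) a raw cloud so that the principal axis of
#' spatial variance lies along X (base to tip), the second axis along Y
#' (chordwise) and the residual axis along Z (thickness). Signs are
#' disambiguated by chord taper (the wingtip end has the smaller chordwise
#' spread, so X increases toward the tip) and by the camber arch (mid-chord
#' points sit above the chord-edge points, so Z increases dorsally); Y is
#' then fixed so the rotation is proper. The transform is rigid: distances
#' are preserved exactly.
#'
#' @param points Numeric n x 3 matrix.
#' @return The aligned n x 3 matrix (centroid at the origin), with the
#'   rotation matrix attached as attribute `"rotation"`.
#' @export
align_pointcloud <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  ctr <- colMeans(points)
  P0 <- sweep(points, 2, ctr)
  s <- svd(P0)
  if (s$d[2] < 1e-12 * s$d[1])
    stop("degenerate point cloud: collinear, cannot align")
  R <- s$v                                   # columns: principal axes
  if (det(R) < 0) R[, 3] <- -R[, 3]
  P <- P0 %*% R

  ## X sign: tip = end with smaller mean chordwise (|Y|) spread
  xr <- range(P[, 1])
  lo <- P[, 1] < xr[1] + 0.25 * diff(xr)
  hi <- P[, 1] > xr[2] - 0.25 * diff(xr)
  spread <- function(v) diff(range(v))
  if (sum(lo) > 1 && sum(hi) > 1 && spread(P[lo, 2]) < spread(P[hi, 2])) {
    P[, 1] <- -P[, 1]; P[, 2] <- -P[, 2]     # rotate 180 deg about Z
  }
  ## Z sign: camber arch opens downward -> mid-chord Z above chord-edge Z
  yr <- range(P[, 2])
  mid <- abs(P[, 2] - mean(yr)) < 0.2 * diff(yr)
  edge <- !mid
  if (sum(mid) > 1 && sum(edge) > 1 &&
      mean(P[mid, 3]) < mean(P[edge, 3])) {
    P[, 3] <- -P[, 3]; P[, 2] <- -P[, 2]     # rotate 180 deg about X
  }
  attr(P, "rotation") <- R
  attr(P, "center") <- ctr
  P
}

#' Slice a wing into chordwise bins along the span
#'
#' Handwing slice width is 1/25th (by default `n_hw` bins) of the wrist-to-tip
#' distance; the same width tiles the armwing from the wrist toward the base.
#' Bins are half-open `[x, x + w)` with the proximal edge inclusive (the
#' distalmost handwing bin is closed so the tip point is kept). The armwing
#' bin adjacent to the joint is labeled `WRIST`.
#'
#' @param scan A `"wing_scan"` with aligned points and `wrist_x` set.
#' @param n_hw Number of handwing slices (default 25).
#' @param min_points Handwing bins with fewer points raise a warning and are
#'   marked empty (default 10).
#' @return A list of class `"wing_slices"`: each element has `slice_index`
#'   (1 = most proximal armwing bin, increasing to the tip), `region`
#'   (`"AW"`, `"WRIST"`, `"HW"`), `points` (the bin's points) and `empty`.
#'   Attributes `width`, `n_aw`, `n_hw`.
#' @export
slice_wing <- function(scan, n_hw = 25L, min_points = 10L) {
  stopifnot(inherits(scan, "wing_scan"))
  P <- scan$points
  P[, 1] <- round(P[, 1], 9)     # bin-stable spanwise coordinates
  xmin <- min(P[, 1]); xmax <- max(P[, 1])
  if (!is.finite(scan$wrist_x)) stop("wrist_x not set")
  if (scan$wrist_x < xmin || scan$wrist_x > xmax)
    stop("wrist_x outside the spanwise extent of the aligned cloud")
  if (scan$wrist_x >= xmax) stop("wrist_x must be proximal to the wingtip")
  w <- (xmax - scan$wrist_x) / n_hw
  n_aw <- floor((scan$wrist_x - xmin) / w)
  edges_aw <- scan$wrist_x - (n_aw:0) * w          # base -> wrist
  edges_hw <- scan$wrist_x + (0:n_hw) * w          # wrist -> tip
  edges <- c(edges_aw[-length(edges_aw)], edges_hw)
  nbin <- length(edges) - 1L
  region <- c(rep("AW", max(n_aw - 1L, 0L)), if (n_aw >= 1L) "WRIST",
              rep("HW", n_hw))
  slices <- vector("list", nbin)
  for (k in seq_len(nbin)) {
    inbin <- P[, 1] >= edges[k] & (P[, 1] < edges[k + 1L] |
                                   (k == nbin & P[, 1] <= edges[k + 1L]))
    pts <- P[inbin, , drop = FALSE]
    empty <- nrow(pts) < min_points
    if (empty && region[k] == "HW")
      warning(sprintf("handwing slice %d has %d < %d points", k, nrow(pts),
                      min_points))
    slices[[k]] <- list(slice_index = k, region = region[k], points = pts,
                        empty = empty)
  }
  structure(slices, class = "wing_slices", width = w, n_aw = n_aw, n_hw = n_hw)
}

#' Measure the four shape traits of one wing slice
#'
#' From the slice's Y/Z projection:
#' * `chord = Y_max - Y_min` (mm);
#' * `camber = (Z_max - Z_min) / (Y_max - Y_min)` using slice-global extremes;
#' * `xst`: maximum upper-to-lower surface distance; by default computed per
#'   chordwise station (Y binned into `n_stations` stations, per-station Z
#'   range minus a midline-slope correction for shell scans, maximum over
#'   stations); `xst_mode = "global"` instead returns the slice-global Z range;
#' * `xsa`: cross-sectional area enclosed by the section outline, computed by
#'   integrating the per-station vertical extent over the chord.
#'
#' `surface = "shell"` (wing scans: points lie on the upper/lower surfaces)
#' applies the slope correction that removes the artificial thickening of a
#' tilted thin section; `surface = "solid"` (points filling the section)
#' integrates the raw per-station extent.
#'
#' @param points n x 3 matrix of one slice's points (n >= 10).
#' @param n_stations Number of chordwise stations (default 100).
#' @param xst_mode `"stations"` (default) or `"global"`.
#' @param surface `"shell"` (default) or `"solid"`.
#' @return A list of class `"slice_traits"`: `camber`, `chord`, `xst`,
#'   `xsa`, `scaled = FALSE`.
#' @export
measure_slice <- function(points, n_stations = 100L,
                          xst_mode = c("stations", "global"),
                          surface = c("shell", "solid")) {
  xst_mode <- match.arg(xst_mode)
  surface <- match.arg(surface)
  if (nrow(points) < 10) stop("need at least 10 points in a slice")
  ## quantize to 1e-9 mm so station binning is stable under the ~1e-12 mm
  ## round-off differences that different rigid-motion histories leave
  y <- round(points[, 2], 9); z <- round(points[, 3], 9)
  chord <- diff(range(y))
  if (chord <= 0) stop("zero chord: camber undefined")
  camber <- diff(range(z)) / chord

  ## station count adapts to density: ~25 points per station keeps the
  ## per-station surface means stable without washing out chordwise detail
  nst <- min(n_stations, max(8L, floor(nrow(points) / 25)))
  st <- pmin(pmax(ceiling((y - min(y)) / chord * nst), 1L), nst)
  w <- chord / nst
  ext <- rep(NA_real_, nst)
  for (k in unique(st)) {
    sel <- st == k
    zk <- z[sel]
    nk <- length(zk)
    ext[k] <- if (surface == "shell" && nk >= 4) {
      ## shell scans: points lie on the upper and lower surfaces, which share
      ## the camber arc; classify by the station midline, fit the arc slope
      ## within each class, and difference the class predictions at the
      ## station center -- this cancels the shared chordwise arc variation
      yk <- y[sel]
      ## initial split on raw z, then re-split on residuals from the pooled
      ## within-class slope: robust on steeply tilted stations near the
      ## chord edges, where the shared arc slope rivals the shell thickness
      up <- zk >= (max(zk) + min(zk)) / 2
      pooled_slope <- function(up) {
        syz <- syy <- 0
        for (cls in list(up, !up)) {
          if (sum(cls) >= 2) {
            syz <- syz + sum((yk[cls] - mean(yk[cls])) * (zk[cls] - mean(zk[cls])))
            syy <- syy + sum((yk[cls] - mean(yk[cls]))^2)
          }
        }
        if (syy > 0) syz / syy else 0
      }
      b0 <- 0
      for (it in 1:2) {
        if (!any(up) || all(up)) break
        b0 <- pooled_slope(up)
        rk <- zk - b0 * yk
        up <- rk >= (max(rk) + min(rk)) / 2
      }
      if (any(up) && any(!up)) {
        ## both surfaces share the arc, so the pooled slope detrends both
        ## classes; per-class fits on few points extrapolate unstably
        ymid <- mean(range(yk))
        at_mid <- function(cls)
          mean(zk[cls]) + b0 * (ymid - mean(yk[cls]))
        max(at_mid(up) - at_mid(!up), 0)
      } else diff(range(zk))
    } else {
      ## solid fill: the sample range of nk uniform draws covers
      ## (nk-1)/(nk+1) of the true extent; undo that bias
      if (nk >= 2) diff(range(zk)) * (nk + 1) / (nk - 1) else 0
    }
  }
  filled <- !is.na(ext)
  xst <- if (xst_mode == "global") {
    diff(range(z))
  } else {
    ## 5-station moving average (partial windows at the ends) before the max
    ## damps the noise-max bias over many stations
    e0 <- ifelse(filled, ext, 0)
    sm <- vapply(seq_len(nst), function(k)
      mean(e0[max(1L, k - 2L):min(nst, k + 2L)]), 0)
    max(sm)
  }
  xsa <- sum(ext[filled]) * w * nst / max(sum(filled), 1L)
  structure(list(camber = camber, chord = chord, xst = xst, xsa = xsa,
                 scaled = FALSE), class = "slice_traits")
}

#' Scale slice traits by body mass
#'
#' Linear measures (chord, xst) are divided by `body_mass^(1/3)`, areas (xsa)
#' by `body_mass^(2/3)`; camber is dimensionless and unchanged.
#'
#' @param traits A `"slice_traits"` object (raw units).
#' @param body_mass Body mass in grams (> 0).
#' @return The mass-scaled `"slice_traits"` (`scaled = TRUE`).
#' @export
scale_by_mass <- function(traits, body_mass) {
  if (!is.finite(body_mass) || body_mass <= 0) stop("body_mass must be > 0")
  if (isTRUE(traits$scaled)) stop("traits already mass-scaled")
  traits$chord <- traits$chord / body_mass^(1 / 3)
  traits$xst <- traits$xst / body_mass^(1 / 3)
  traits$xsa <- traits$xsa / body_mass^(2 / 3)
  traits$scaled <- TRUE
  traits
}

#' Undo mass scaling (round-trip exact)
#'
#' @inheritParams scale_by_mass
#' @export
unscale_by_mass <- function(traits, body_mass) {
  if (!isTRUE(traits$scaled)) stop("traits are not mass-scaled")
  traits$chord <- traits$chord * body_mass^(1 / 3)
  traits$xst <- traits$xst * body_mass^(1 / 3)
  traits$xsa <- traits$xsa * body_mass^(2 / 3)
  traits$scaled <- FALSE
  traits
}

#' Measure a whole wing scan
#'
#' Aligns (optionally), slices, measures and mass-scales one scan, returning
#' a per-slice trait table.
#'
#' @param scan A `"wing_scan"`.
#' @param n_hw Number of handwing slices.
#' @param align Align the cloud first? Set `FALSE` if already in the
#'   measurement frame.
#' @param scale Mass-scale the linear/area traits?
#' @param ... Passed to [measure_slice()].
#' @return A data.frame with one row per slice: `slice_index`, `region`,
#'   `camber`, `chord`, `xst`, `xsa`, `n_points`; empty slices carry `NA`.
#' @export
measure_wing <- function(scan, n_hw = 25L, align = FALSE, scale = TRUE, ...) {
  if (align) {
    P <- align_pointcloud(scan$points)
    scan$points <- P
  }
  slices <- slice_wing(scan, n_hw = n_hw)
  rows <- lapply(slices, function(s) {
    if (s$empty) {
      data.frame(slice_index = s$slice_index, region = s$region,
                 camber = NA_real_, chord = NA_real_, xst = NA_real_,
                 xsa = NA_real_, n_points = nrow(s$points))
    } else {
      tr <- measure_slice(s$points, ...)
      if (scale) tr <- scale_by_mass(tr, scan$body_mass)
      data.frame(slice_index = s$slice_index, region = s$region,
                 camber = tr$camber, chord = tr$chord, xst = tr$xst,
                 xsa = tr$xsa, n_points = nrow(s$points))
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "species_id") <- scan$species_id
  attr(out, "specimen_id") <- scan$specimen_id
  out
}

#' Species-median trait profiles from per-specimen slice tables
#'
#' Maps every specimen's slices onto the common standardized index (counted
#' from the wrist: 25 handwing slices distal, wrist bin, 10 armwing slices
#' proximal) and takes the per-species, per-slice, per-trait median over
#' specimens.
#'
#' @param tables A list of per-specimen data.frames from [measure_wing()]
#'   (each carrying a `species_id` attribute, or supply `species`).
#' @param species Optional character vector of species ids, one per table.
#' @param n_aw Number of armwing slices to retain proximal to the wrist
#'   (default 10).
#' @param n_hw Number of handwing slices (default 25).
#' @return A named list of `"trait_profile"` objects (camber, chord, xst,
#'   xsa), each species x (n_aw + 1 + n_hw) with regions
#'   `AW...AW WRIST HW...HW`. Species whose armwing has fewer than `n_aw`
#'   usable slices are excluded with a message.
#' @export
summarize_species <- function(tables, species = NULL, n_aw = 10L, n_hw = 25L) {
  if (is.null(species))
    species <- vapply(tables, function(t) attr(t, "species_id"), "")
  if (anyNA(species) || any(species == ""))
    stop("species ids missing; supply `species`")
  traits <- c("camber", "chord", "xst", "xsa")
  p <- n_aw + 1L + n_hw
  ## reindex each specimen: wrist bin at position n_aw + 1
  mats <- lapply(tables, function(tb) {
    wi <- which(tb$region == "WRIST")
    if (length(wi) != 1L) return(NULL)
    pos <- tb$slice_index - tb$slice_index[wi] + n_aw + 1L
    keep <- pos >= 1L & pos <= p
    m <- matrix(NA_real_, p, length(traits), dimnames = list(NULL, traits))
    for (tr in traits) m[pos[keep], tr] <- tb[[tr]][keep]
    m
  })
  ok <- !vapply(mats, is.null, TRUE)
  mats <- mats[ok]; species <- species[ok]
  sp <- sort(unique(species))
  out <- lapply(traits, function(tr) {
    vals <- t(vapply(sp, function(s) {
      block <- vapply(mats[species == s], function(m) m[, tr], numeric(p))
      apply(matrix(block, nrow = p), 1, stats::median, na.rm = TRUE)
    }, numeric(p)))
    rownames(vals) <- sp
    vals
  })
  names(out) <- traits
  ## exclude species with incomplete armwing coverage
  usable <- rowSums(!is.na(out$chord[, seq_len(n_aw), drop = FALSE])) >= n_aw
  if (any(!usable))
    message("excluding species with < ", n_aw, " usable armwing slices: ",
            paste(sp[!usable], collapse = ", "))
  regions <- c(rep("AW", n_aw), "WRIST", rep("HW", n_hw))
  lapply(stats::setNames(traits, traits), function(tr)
    trait_profile(out[[tr]][usable, , drop = FALSE], trait = tr,
                  regions = regions, scaled = TRUE))
}

#' Standardize trait profiles for analysis
#'
#' Applies the wrist policy (default: exclude the wrist bin, giving 10 AW +
#' 25 HW = 35 slices), optionally log10-transforms, and drops species with
#' missing values.
#'
#' @param profiles A single `"trait_profile"` or a named list of them.
#' @param wrist_policy `"excluded"`, `"to_HW"` or `"to_AW"`.
#' @param log10 Apply the log10 transform (used for the modularity test)?
#' @param drop_incomplete Drop species rows containing `NA`?
#' @return Standardized profile(s), same shape of input.
#' @export
standardize_profiles <- function(profiles, wrist_policy = "excluded",
                                 log10 = FALSE, drop_incomplete = TRUE) {
  one <- function(pr) {
    pr <- apply_wrist_policy(pr, wrist_policy)
    if (log10) pr <- log10_profile(pr)
    if (drop_incomplete) {
      bad <- rowSums(is.na(pr$values)) > 0
      if (any(bad)) {
        message("excluding species with missing slices: ",
                paste(rownames(pr$values)[bad], collapse = ", "))
        pr$values <- pr$values[!bad, , drop = FALSE]
      }
    }
    pr
  }
  if (inherits(profiles, "trait_profile")) one(profiles) else lapply(profiles, one)
}
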