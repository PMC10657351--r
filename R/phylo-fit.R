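#' Multivariate-normal log-likelihood for tip data on a tree
#'
#' Log density of tip values `x` under a Gaussian trait model with mean
#' `z0 * 1` and covariance `V`, evaluated via the Cholesky factorization.
#'
#' @param x Numeric vector of tip values (order matching `V`).
#' @param V Positive-definite covariance matrix.
#' @param z0 Root (ancestral) state.
#' @return The log-likelihood (scalar).
#' @export
phylo_loglik <- function(x, V, z0) {
  n <- length(x)
  if (nrow(V) != n) stop("dimension mismatch between x and V")
  L <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite"))
  logdet <- 2 * sum(log(diag(L)))
  e <- backsolve(L, x - z0, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + logdet + sum(e^2))
}

## GLS profile of (z0, sigma2) given the unit-rate structure matrix V0:
##   z0hat = (1' V0^-1 1)^-1 1' V0^-1 x,  sigma2hat = Q/n (ML divisor),
## and the resulting profile log-likelihood. Returns the pieces the model
## fitters need. Cholesky-based; O(n^2) once the factor exists.
gls_profile <- function(x, V0) {
  n <- length(x)
  L <- chol(V0)
  logdet <- 2 * sum(log(diag(L)))
  ones <- rep(1, n)
  w1 <- backsolve(L, ones, transpose = TRUE)
  wx <- backsolve(L, x, transpose = TRUE)
  denom <- sum(w1^2)
  z0 <- sum(w1 * wx) / denom
  Q <- sum((wx - z0 * w1)^2)
  sigma2 <- Q / n
  degenerate <- sigma2 < .Machine$double.eps * max(diag(V0))
  s2 <- max(sigma2, .Machine$double.xmin)  # documented floor for constant data
  loglik <- -0.5 * n * (log(2 * pi) + log(s2) + 1) - 0.5 * logdet
  list(z0 = z0, sigma2 = sigma2, loglik = loglik, logdet = logdet,
       degenerate = degenerate)
}

#' AICc of a fitted model
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (tips).
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a continuous-trait evolutionary model by maximum likelihood
#'
#' Fits Brownian motion (BM), Ornstein-Uhlenbeck (OU, fixed-root
#' non-stationary) or early-burst (EB) to tip data on a rooted tree with
#' branch lengths. The root state and rate are profiled analytically by GLS;
#' the OU pull `alpha` or EB decay `r` is found by bounded one-dimensional
#' optimization of the profile likelihood over four bracketing intervals
#' (log-spaced multi-starts), so the fit is deterministic.
#'
#' Parameter bounds (in units of the inverse tree depth):
#' `alpha` in `[0, 50/depth]`, `r` in `[-10/depth, 0]`.
#'
#' @param x Named numeric vector of tip values.
#' @param tree A `"phylo"` object.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param C Optional precomputed shared-time matrix (as from
#'   `phylo_cov(tree, "BM")`), to amortize work across slices.
#' @return An object of class `"evol_fit"`: a list with `model`, `sigma2`,
#'   `z0`, `alpha`/`r_eb` where relevant, `loglik`, `aicc`, `n_params`, `n`,
#'   and flags `at_bound` and `degenerate`.
#' @export
fit_model <- function(x, tree, model = c("BM", "OU", "EB"), C = NULL) {
  model <- match.arg(model)
  if (is.null(C)) {
    x <- align_tips(x, tree)
    C <- shared_time_matrix(tree)
  } else if (!is.null(names(x)) && !is.null(rownames(C))) {
    x <- x[rownames(C)]
  }
  n <- length(x)
  min_n <- if (model == "BM") 2L else 4L
  if (n < min_n) stop("need at least ", min_n, " tips for ", model)
  if (!all(is.finite(x))) stop("non-finite trait values")
  depth <- max(diag(C))

  fit <- switch(model,
    BM = {
      g <- gls_profile(x, C)
      list(par = NULL, g = g, at_bound = FALSE)
    },
    OU = {
      obj <- function(a) gls_profile(x, ou_structure(C, a))$loglik
      opt <- profile_optimize(obj, lower = 0, upper = 50 / depth,
                              starts = c(1e-4, 1e-2, 1, 10) / depth)
      list(par = c(alpha = opt$par), g = gls_profile(x, ou_structure(C, opt$par)),
           at_bound = opt$at_bound)
    },
    EB = {
      obj <- function(r) gls_profile(x, eb_structure(C, r))$loglik
      opt <- profile_optimize(obj, lower = -10 / depth, upper = 0,
                              starts = -c(1e-4, 1e-2, 1, 5) / depth)
      list(par = c(r_eb = opt$par), g = gls_profile(x, eb_structure(C, opt$par)),
           at_bound = opt$at_bound)
    }
  )
  k <- if (model == "BM") 2L else 3L
  if (!is.finite(fit$g$loglik)) stop("non-finite likelihood in ", model, " fit")
  out <- list(model = model, sigma2 = fit$g$sigma2, z0 = fit$g$z0,
              alpha = unname(fit$par["alpha"]), r_eb = unname(fit$par["r_eb"]),
              loglik = fit$g$loglik, n_params = k, n = n,
              aicc = if (n - k - 1 > 0) aicc(fit$g$loglik, k, n) else NA_real_,
              at_bound = isTRUE(fit$at_bound),
              degenerate = isTRUE(fit$g$degenerate))
  class(out) <- "evol_fit"
  out
}

#' @export
print.evol_fit <- function(x, ...) {
  cat(sprintf("%s fit: sigma2 = %.6g, z0 = %.6g", x$model, x$sigma2, x$z0))
  if (!is.null(x$alpha) && !is.na(x$alpha)) cat(sprintf(", alpha = %.6g", x$alpha))
  if (!is.null(x$r_eb) && !is.na(x$r_eb)) cat(sprintf(", r = %.6g", x$r_eb))
  cat(sprintf("\n  loglik = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$loglik, x$aicc, x$n_params, x$n))
  if (x$at_bound) cat("  note: parameter estimate at bound\n")
  if (x$degenerate) cat("  note: degenerate (constant) data; sigma2 = 0\n")
  invisible(x)
}

## Bounded 1-D maximization with bracketing multi-starts: the interval
## [lower, upper] is cut at the start points and stats::optimize() is run in
## each sub-interval; the best optimum (or boundary point) wins.
profile_optimize <- function(f, lower, upper, starts, tol = 1e-8) {
  cuts <- sort(unique(pmin(pmax(starts, lower), upper)))
  brks <- unique(c(lower, cuts, upper))
  best <- list(par = lower, val = f(lower))
  up_val <- f(upper)
  if (up_val > best$val) best <- list(par = upper, val = up_val)
  for (i in seq_len(length(brks) - 1L)) {
    o <- stats::optimize(f, lower = brks[i], upper = brks[i + 1L],
                         maximum = TRUE, tol = tol * max(abs(upper), 1))
    if (o$objective > best$val) best <- list(par = o$maximum, val = o$objective)
  }
  span <- upper - lower
  at_bound <- (best$par - lower) < 1e-6 * span || (upper - best$par) < 1e-6 * span
  ## treat the zero end (BM limit) as a valid interior solution, not a bound,
  ## when it is the model-reduction boundary
  list(par = best$par, value = best$val, at_bound = at_bound)
}

#' Select the best evolutionary model by AICc
#'
#' @param fits A list of `"evol_fit"` objects for the same data.
#' @return A list with `best` (the winning fit), `table` (a data.frame of
#'   model, loglik, k, AICc, delta_aicc sorted by AICc). Ties within 1e-6 are
#'   broken toward fewer parameters.
#' @export
model_select <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    k = vapply(fits, `[[`, 0L, "n_params"),
    aicc = vapply(fits, `[[`, 0, "aicc")
  )
  ord <- order(tab$aicc, tab$k)   # parsimony tie-break
  best_i <- ord[1L]
  if (tab$aicc[ord[2L]] - tab$aicc[best_i] < 1e-6 && nrow(tab) > 1L) {
    cand <- which(tab$aicc - tab$aicc[best_i] < 1e-6)
    best_i <- cand[which.min(tab$k[cand])]
  }
  tab$delta_aicc <- tab$aicc - tab$aicc[best_i]
  list(best = fits[[best_i]], table = tab[order(tab$aicc, tab$k), ])
}

#' Per-slice evolutionary rate profile
#'
#' Fits evolutionary models at every wing slice of a trait profile and
#' returns the spanwise series of rate estimates (sigma^2). Under the default
#' policy each slice gets BM, OU and EB fits and sigma^2 is taken from the
#' slice's AICc-best model; `model_policy = "BM"|"OU"|"EB"` forces one model
#' everywhere.
#'
#' @param profile A `"trait_profile"` (see [trait_profile()]) or a species x
#'   slice numeric matrix with species as rownames.
#' @param tree A `"phylo"` object containing all species.
#' @param model_policy `"best_aicc"` (default) or a forced model name.
#' @return A data.frame of class `"span_profile"` with columns `slice`
#'   (1-based position, base to tip), `region`, `value` (sigma^2), `model`,
#'   `delta_aicc_next` (margin over the runner-up) and `at_bound`.
#' @export
sigma2_profile <- function(profile, tree,
                           model_policy = c("best_aicc", "BM", "OU", "EB")) {
  model_policy <- match.arg(model_policy)
  m <- as_profile_matrix(profile)
  regions <- profile_regions(profile, ncol(m))
  tree <- prune_tree(tree, rownames(m))
  C <- shared_time_matrix(tree)
  m <- m[rownames(C), , drop = FALSE]
  out <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (anyNA(x)) {
      message("slice ", j, " skipped: missing species values")
      out[[j]] <- data.frame(slice = j, region = regions[j], value = NA_real_,
                             model = NA_character_, delta_aicc_next = NA_real_,
                             at_bound = NA)
      next
    }
    if (model_policy == "best_aicc") {
      fits <- lapply(c("BM", "OU", "EB"), function(mod)
        fit_model(x, tree, mod, C = C))
      sel <- model_select(fits)
      fit <- sel$best
      dnext <- sel$table$delta_aicc[2L]
    } else {
      fit <- fit_model(x, tree, model_policy, C = C)
      dnext <- NA_real_
    }
    out[[j]] <- data.frame(slice = j, region = regions[j], value = fit$sigma2,
                           model = fit$model, delta_aicc_next = dnext,
                           at_bound = fit$at_bound)
  }
  res <- do.call(rbind, out)
  class(res) <- c("span_profile", "data.frame")
  attr(res, "statistic") <- "sigma2"
  res
}

#' Per-slice phylogenetic signal profile
#'
#' Computes Blomberg's K and Pagel's lambda for every slice of a trait
#' profile.
#'
#' @inheritParams sigma2_profile
#' @return A data.frame with columns `slice`, `region`, `blomberg_k`,
#'   `pagel_lambda`.
#' @export
signal_profile <- function(profile, tree) {
  m <- as_profile_matrix(profile)
  regions <- profile_regions(profile, ncol(m))
  tree <- prune_tree(tree, rownames(m))
  C <- shared_time_matrix(tree)
  m <- m[rownames(C), , drop = FALSE]
  k <- lam <- rep(NA_real_, ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (anyNA(x)) next
    k[j] <- blomberg_k(x, tree, C = C)
    lam[j] <- pagel_lambda(x, tree, C = C)$lambda
  }
  data.frame(slice = seq_len(ncol(m)), region = regions,
             blomberg_k = k, pagel_lambda = lam)
}
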