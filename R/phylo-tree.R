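#' Read a phylogeny from a Newick file or string
#'
#' Thin wrapper around [ape::read.tree()] that validates the properties the
#' comparative machinery in this package needs: unique tip labels and branch
#' lengths present and non-negative.
#'
#' @param source Path to a Newick file, or a character string containing a
#'   Newick description (detected by the presence of `"("`).
#' @return An object of class `"phylo"`.
#' @export
read_newick <- function(source) {
  tr <- if (length(source) == 1L && grepl("(", source, fixed = TRUE)) {
    ape::read.tree(text = source)
  } else {
    ape::read.tree(source)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  validate_phylo(tr)
  tr
}

#' Read a set of trees (e.g. a posterior sample)
#'
#' Reads either a multi-tree Newick file or a Nexus trees block.
#'
#' @param path File path; Nexus files are detected by a leading `#NEXUS`.
#' @return A list of `"phylo"` objects (class `"multiPhylo"`).
#' @export
read_tree_set <- function(path) {
  first <- readLines(path, n = 1L)
  trs <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(trs, "phylo")) trs <- c(structure(list(trs), class = "multiPhylo"))
  trs
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  if (any(tree$edge.length == 0 & tree$edge[, 2] <= length(tree$tip.label)))
    warning("zero-length terminal branches in tree")
  invisible(tree)
}

#' Prune a phylogeny to a set of tip labels
#'
#' Removes all tips not in `labels` and suppresses the resulting degree-2
#' nodes, summing branch lengths, so that path lengths among retained tips
#' are preserved.
#'
#' @param tree A `"phylo"` object.
#' @param labels Character vector of tip labels to retain.
#' @return The pruned `"phylo"` object.
#' @export
prune_tree <- function(tree, labels) {
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing))
    stop("labels absent from tree: ", paste(missing, collapse = ", "))
  drop <- setdiff(tree$tip.label, labels)
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop)
}

## Node heights above the root, computed by a preorder sweep of the edge
## matrix (root has height 0).
node_heights <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  h <- numeric(n + m)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  for (i in seq_len(nrow(tr$edge))) {
    h[tr$edge[i, 2]] <- h[tr$edge[i, 1]] + tr$edge.length[i]
  }
  h
}

#' Phylogenetic covariance matrix under BM, OU or EB
#'
#' Builds the among-tip trait covariance matrix implied by a rooted tree with
#' branch lengths under one of three evolutionary models.
#'
#' * `BM`: `C[i, j]` is the shared path length from the root (height of the
#'   most recent common ancestor of tips i and j); the diagonal holds
#'   root-to-tip distances. Covariance is `sigma2 * C`.
#' * `OU` (fixed root, non-stationary, the convention of common
#'   maximum-likelihood fits on ultrametric trees):
#'   `V[i, j] = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha s_ij))`
#'   with `s_ij` the shared time and `d_ij` the patristic distance.
#' * `EB`: a branch segment at height t contributes `exp(r t) dt`, so the
#'   shared-path integral is `(exp(r s_ij) - 1)/r` (times `sigma2`).
#'
#' Both the OU (`alpha -> 0`) and EB (`r -> 0`) limits reduce continuously to
#' the BM matrix.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param model One of `"BM"`, `"OU"`, `"EB"`.
#' @param sigma2 Diffusion rate multiplying the unit-rate structure matrix.
#' @param alpha OU pull strength (>= 0), per unit time.
#' @param r_eb EB exponential rate-change parameter (<= 0), per unit time.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_cov <- function(tree, model = c("BM", "OU", "EB"), sigma2 = 1,
                      alpha = 0, r_eb = 0) {
  model <- match.arg(model)
  if (alpha < 0) stop("alpha must be >= 0")
  if (r_eb > 0) stop("r_eb must be <= 0")
  C <- shared_time_matrix(tree)
  V <- switch(model,
    BM = C,
    OU = ou_structure(C, alpha),
    EB = eb_structure(C, r_eb)
  )
  sigma2 * V
}

## Shared-time (BM unit-rate) matrix: C_ij = height of mrca(i, j).
shared_time_matrix <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  h <- node_heights(tree)
  mr <- ape::mrca(tree)
  C <- matrix(h[mr], n, n)
  diag(C) <- h[seq_len(n)]
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

ou_structure <- function(C, alpha) {
  if (alpha == 0) return(C)
  ti <- diag(C)
  D <- outer(ti, ti, "+") - 2 * C          # patristic distances
  V <- exp(-alpha * D) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
  dimnames(V) <- dimnames(C)
  V
}

eb_structure <- function(C, r_eb) {
  if (r_eb == 0) return(C)
  V <- (exp(r_eb * C) - 1) / r_eb
  dimnames(V) <- dimnames(C)
  V
}

#' Resolve polytomies to zero-length branches
#'
#' @param tree A `"phylo"` object.
#' @return A fully bifurcating `"phylo"` object with identical tip-to-tip
#'   path lengths.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tr <- ape::multi2di(tree, random = FALSE)
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

## Align a named data vector with a tree's tips; error on mismatch.
align_tips <- function(x, tree) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label))
      stop("unnamed data vector of wrong length")
    names(x) <- tree$tip.label
    return(x)
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("data missing for tips: ", paste(miss, collapse = ", "))
  x[tree$tip.label]
}
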