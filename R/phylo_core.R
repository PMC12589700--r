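#' Read phylogenetic trees from a Newick file
#'
#' Reads one or many trees (one per `;`-terminated statement) and validates
#' that every tip is labelled and every edge carries a branch length.
#'
#' @param newick_source Path to a Newick file, or a Newick string.
#' @return A list of `phylo` objects (even for a single tree).
#' @export
read_trees <- function(newick_source) {
  if (length(newick_source) == 1 && !grepl(";", newick_source, fixed = TRUE) &&
      !file.exists(newick_source)) {
    stop("`newick_source` is neither an existing file nor a Newick string",
         call. = FALSE)
  }
  trees <- if (file.exists(newick_source)) {
    ape::read.tree(file = newick_source)
  } else {
    ape::read.tree(text = newick_source)
  }
  if (is.null(trees)) stop("could not parse any tree from input", call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
        anyNA(tr$edge.length)) {
      stop(sprintf("tree %d: every edge must have a branch length", i),
           call. = FALSE)
    }
    labs <- trimws(tr$tip.label)
    if (any(labs == "") || anyNA(labs)) {
      stop(sprintf("tree %d: unlabeled tips are not allowed", i), call. = FALSE)
    }
    if (anyDuplicated(labs)) {
      stop(sprintf("tree %d: duplicated tip labels", i), call. = FALSE)
    }
    tr$tip.label <- labs
    trees[[i]] <- tr
  }
  trees
}

#' Prune a tree to a set of tip labels
#'
#' Keeps exactly the requested tips; internal degree-2 nodes left behind are
#' collapsed with their branch lengths summed, so root-to-tip distances are
#' preserved.
#'
#' @param tree A `phylo` object.
#' @param labels Character vector of tip labels to keep (whitespace-trimmed,
#'   exact matching).
#' @return The pruned `phylo` object.
#' @export
prune_to <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  labels <- trimws(labels)
  missing <- setdiff(labels, trimws(tree$tip.label))
  if (length(missing) > 0) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop <- setdiff(tree$tip.label, labels)
  if (length(drop) == 0) return(tree)
  out <- ape::keep.tip(tree, labels)
  # keep the stem between the old root and the new one as a root edge so
  # root-to-tip distances (and hence Brownian covariances) are preserved
  ref <- labels[1]
  d_orig <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
  d_new <- ape::node.depth.edgelength(out)[match(ref, out$tip.label)]
  stem <- (tree$root.edge %||% 0) + d_orig - d_new
  if (stem > 1e-12) out$root.edge <- stem
  out
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' shared branch length from the root to their most recent common ancestor;
#' the variance of a tip is its root-to-tip distance.
#'
#' @param tree A rooted `phylo` object with non-negative branch lengths.
#' @return A `phylo_cov` object: list with `tip_labels`, the matrix `C`
#'   (tips x tips, in tree-distance units) and `lambda` (1, the untransformed
#'   Brownian expectation).
#' @export
brownian_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  C <- ape::vcv.phylo(tree)
  # a retained root edge is history shared by every tip
  re <- tree$root.edge
  if (length(re) == 1 && is.finite(re) && re > 0) C <- C + re
  new_phylo_cov(C, lambda = 1)
}

new_phylo_cov <- function(C, lambda = 1) {
  structure(
    list(tip_labels = rownames(C), C = C, lambda = lambda),
    class = "phylo_cov"
  )
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("<phylo_cov> %d tips, lambda = %g\n", nrow(x$C), x$lambda))
  invisible(x)
}

# Pagel's lambda transform on a plain covariance matrix: off-diagonals
# multiplied by lambda, diagonal untouched.
lambda_scale <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies the off-diagonal (shared-history) entries of the covariance by
#' `lambda` while keeping tip variances unchanged. `lambda = 1` leaves the
#' Brownian expectation intact; `lambda = 0` removes all phylogenetic
#' covariance.
#'
#' @param pc A `phylo_cov` object (see [brownian_vcv()]).
#' @param lambda Scalar in `[0, lambda_max]`.
#' @param lambda_max Upper bound for `lambda`; defaults to 1, the
#'   conventional Pagel range (for ultrametric trees any value up to 1 keeps
#'   the matrix positive-definite).
#' @return A `phylo_cov` with the transformed matrix and `lambda` recorded.
#' @export
lambda_transform <- function(pc, lambda, lambda_max = 1) {
  stopifnot(inherits(pc, "phylo_cov"))
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0 || lambda > lambda_max) {
    stop(sprintf("`lambda` must lie in [0, %g]", lambda_max), call. = FALSE)
  }
  out <- new_phylo_cov(lambda_scale(pc$C, lambda), lambda = lambda)
  out
}

# Align a phylo_cov to a vector of species labels (reorders C); errors on
# any mismatch. Used by every fitting routine so data and covariance rows
# always correspond.
align_phylo_cov <- function(pc, species) {
  species <- trimws(as.character(species))
  missing <- setdiff(species, pc$tip_labels)
  if (length(missing) > 0) {
    stop("species absent from phylogeny: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  C <- pc$C[species, species, drop = FALSE]
  new_phylo_cov(C, lambda = pc$lambda)
}
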