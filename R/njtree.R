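#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on a fully defined distance matrix,
#' typically Jukes-Cantor corrected distances from [distance_matrix()].
#' Negative branch lengths (a well-known NJ artifact on noisy matrices) are
#' clamped to zero and the total clamped deficit reported as a warning.
#'
#' @param dm An `ed_dist` object or a symmetric numeric matrix with
#'   dimnames; all off-diagonal entries must be defined.
#' @return An unrooted `phylo` tree (trifurcating root representation) with
#'   leaf labels equal to the matrix ids.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "ed_dist")) dm$d else as.matrix(dm)
  if (is.null(rownames(d))) stop("distance matrix must carry ids as dimnames")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(d[upper.tri(d)])) {
    stop("distance matrix contains undefined pairs; lower min_overlap ",
         "requirements are not met for some pairs - prune those taxa or ",
         "recompute with a smaller min_overlap")
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    deficit <- -sum(tr$edge.length[neg])
    tr$edge.length[neg] <- 0
    warning(sprintf("clamped %d negative branch length(s), total deficit %.6g",
                    sum(neg), deficit))
  }
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the internal bipartition sets; 0 means identical
#' unrooted topologies.
#'
#' @param treeA,treeB `phylo` objects over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(treeA, treeB) {
  stopifnot(inherits(treeA, "phylo"), inherits(treeB, "phylo"))
  if (!setequal(treeA$tip.label, treeB$tip.label)) {
    stop("trees have different leaf sets")
  }
  as.integer(phangorn::RF.dist(ape::unroot(treeA), ape::unroot(treeB)))
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
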