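#' Scale a tree to height 1
#'
#' Divides all branch lengths by the tree height (maximum root-to-tip
#' distance), the normalization used before comparing estimated and true
#' species trees, so distances are comparable across analyses with
#' different absolute scales.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return The tree with height exactly 1; relative branch proportions
#'   are unchanged.
#' @export
normalize_height <- function(tree) {
  h <- tree_height(tree)
  if (h <= 0) stop("tree height is zero; cannot normalize", call. = FALSE)
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Height (maximum root-to-tip distance) of a tree
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return The largest root-to-tip path length.
#' @export
tree_height <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_node <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n_node)
  for (e in seq_len(nrow(tree$edge)))
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + tree$edge.length[e]
  max(depth[seq_along(tree$tip.label)])
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets", call. = FALSE)
}

#' Branch score distance between two trees
#'
#' Kuhner–Felsenstein branch score: the square root of the sum, over the
#' union of bipartitions of the two (unrooted) trees, of squared
#' branch-length differences, with length 0 for a split absent from one
#' tree.  Pendant branches are included.
#'
#' @param t1,t2 `phylo` trees on the same leaf set, with branch lengths.
#' @param normalize Scale both trees to height 1 first (default `FALSE`).
#' @return Nonnegative distance.
#' @export
branch_score_distance <- function(t1, t2, normalize = FALSE) {
  check_same_leaves(t1, t2)
  if (normalize) { t1 <- normalize_height(t1); t2 <- normalize_height(t2) }
  if (length(t1$tip.label) == 2L) {
    # a two-leaf unrooted tree is a single edge: compare total lengths
    return(abs(sum(t1$edge.length) - sum(t2$edge.length)))
  }
  u1 <- ape::unroot(t1); u2 <- ape::unroot(t2)
  as.numeric(phangorn::KF.dist(u1, u2))
}

#' Robinson–Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the
#' two unrooted trees.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return Integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  check_same_leaves(t1, t2)
  if (length(t1$tip.label) < 4L) return(0L)  # no non-trivial splits
  u1 <- ape::unroot(t1); u2 <- ape::unroot(t2)
  as.integer(phangorn::RF.dist(u1, u2))
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree:
# each split is the sorted tip subset not containing the first tip label
# (alphabetically), so keys are orientation-independent.
tree_splits <- function(tree, keep_trivial = FALSE) {
  if (length(tree$tip.label) < 4L) return(character(0))
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  keys <- vapply(bp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, "")
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, 1L)
  keep <- keys != "" & sizes >= 2L & sizes <= length(tips) - 2L
  unique(keys[keep])
}
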