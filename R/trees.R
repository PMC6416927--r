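#' Read a gene-family tree from a newick file
#'
#' Trees are the backbone for ancestral-state inference: leaves are extant
#' gene IDs and branch lengths are on the scale of the alignment the tree was
#' estimated from (typically amino-acid substitutions per site). Branch
#' lengths are mandatory because the Markov transition kernel along each edge
#' depends on them.
#'
#' @param path Path to a newick file. May contain one tree.
#' @param text Newick string, as an alternative to `path`.
#' @return An [ape::phylo] object. Unrooted trees are returned as parsed;
#'   root them with [midpoint_root()] before inference.
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick input")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, got several")
  validate_tree(tr)
  tr
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    # name an offending edge so the user can find it in the file
    miss <- if (is.null(tree$edge.length)) 1L else which(is.na(tree$edge.length))[1]
    child <- tree$edge[miss, 2]
    lab <- if (child <= length(tree$tip.label)) tree$tip.label[child] else paste0("node_", child)
    stop("missing branch length on the edge leading to '", lab, "'")
  }
  if (anyNA(tree$edge.length)) {
    child <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    lab <- if (child <= length(tree$tip.label)) tree$tip.label[child] else paste0("node_", child)
    stop("missing branch length on the edge leading to '", lab, "'")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ", tree$tip.label[anyDuplicated(tree$tip.label)])
  }
  invisible(tree)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. This is
#' the standard fallback when no reliable outgroup exists, as is typical for
#' plant TF families where homologs from repeated duplications interleave.
#'
#' @param tree A `phylo` object, rooted or not.
#' @return A rooted `phylo`; leaf-to-leaf path lengths are preserved.
#' @export
midpoint_root <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves")
  if (sum(tree$edge.length) == 0) {
    warning("tree has zero total length; returning unchanged")
    return(tree)
  }
  rooted <- phangorn::midpoint(tree)
  # midpoint() can return tiny negative rounding artefacts on the new root edges
  rooted$edge.length[rooted$edge.length < 0 & rooted$edge.length > -1e-12] <- 0
  rooted
}

#' Root-to-leaf distances
#'
#' @param tree A rooted `phylo`.
#' @return Named numeric vector of distances from the root to every leaf.
#' @export
root_to_leaf_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  depth <- numeric(n_tip + tree$Nnode)
  ord <- reorder(tree, "postorder")
  # preorder accumulation: walk edges parent-before-child
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (i in seq_len(nrow(edges))) {
    depth[edges[i, 2]] <- depth[edges[i, 1]] + lens[i]
  }
  setNames(depth[seq_len(n_tip)], tree$tip.label)
}
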