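# Tree input/output and validation.
#
# All trees are rooted, strictly binary, ultrametric ape "phylo" objects.
# Node ages are in My before present; tips sit at age 0.

#' Read and validate an ultrametric tree
#'
#' Reads a newick file and checks the invariants every downstream likelihood
#' assumes: rooted binary topology, branch lengths present and positive, and
#' contemporaneous tips (ultrametricity within a relative tolerance).
#'
#' @param path Path to a newick file with branch lengths.
#' @param tol Relative ultrametricity tolerance; tip depths may differ from
#'   the root age by at most `tol * root_age`. Absorbs newick rounding.
#' @return An object of class `phylo` that passed validation, with attribute
#'   `root_age` (My).
#' @export
read_ultrametric_tree <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick file: ", path)
  validate_ultrametric_tree(phy, tol = tol)
}

#' Write a tree to newick
#'
#' @param phy A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ultrametric_tree <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Validate the ultrametric-tree invariants
#'
#' @param phy A `phylo` object.
#' @param tol Relative ultrametricity tolerance (see [read_ultrametric_tree()]).
#' @return `phy` with attribute `root_age` set, or an error.
#' @export
validate_ultrametric_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("tip labels are not unique")
  n_tip <- length(phy$tip.label)
  if (!ape::is.rooted(phy) || phy$Nnode != n_tip - 1) {
    stop("tree is not rooted and strictly binary; polytomies would corrupt ",
         "the birth-death likelihoods and are rejected rather than resolved")
  }
  if (any(phy$edge.length <= 0)) stop("all branch lengths must be > 0")
  depth <- ape::node.depth.edgelength(phy)
  n_tip <- length(phy$tip.label)
  root_age <- max(depth[seq_len(n_tip)])
  if (root_age <= 0) stop("root age must be > 0")
  if (max(abs(depth[seq_len(n_tip)] - root_age)) > tol * root_age) {
    stop(sprintf(
      "tree is not ultrametric: tip depths span %.6g-%.6g (tolerance %.3g)",
      min(depth[seq_len(n_tip)]), root_age, tol * root_age))
  }
  attr(phy, "root_age") <- root_age
  phy
}

#' Node ages of a tree
#'
#' Ages in My before present for all nodes (tips then internal nodes, in
#' ape's node numbering). Tip ages are forced to exactly 0.
#'
#' @param phy A validated `phylo` object.
#' @return Numeric vector of length `n_tips + n_internal`.
#' @export
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  n_tip <- length(phy$tip.label)
  age <- max(depth[seq_len(n_tip)]) - depth
  age[seq_len(n_tip)] <- 0
  age
}

#' Root age of a tree
#' @param phy A validated `phylo` object.
#' @return Root age in My.
#' @export
root_age <- function(phy) {
  ra <- attr(phy, "root_age")
  if (is.null(ra)) ra <- max(node_ages(phy))
  ra
}

#' Sorted branching times
#'
#' The n-1 internal-node ages of an n-tip tree, sorted descending so that the
#' first element is the root age. These are the sufficient data (beyond tip
#' count) for every time-only birth-death likelihood in the package.
#'
#' @param phy A validated `phylo` object.
#' @return Numeric vector of length `n_tips - 1`, descending.
#' @export
branching_times <- function(phy) {
  n_tip <- length(phy$tip.label)
  age <- node_ages(phy)
  sort(age[(n_tip + 1):length(age)], decreasing = TRUE)
}

#' Prune a tree to a set of species
#'
#' Restricts the tree to `keep` (intersected with the tip set), suppressing
#' unary nodes and preserving node ages, so the result is again ultrametric.
#'
#' @param phy A validated `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned, re-validated `phylo`.
#' @export
prune_to_set <- function(phy, keep) {
  keep <- intersect(phy$tip.label, keep)
  if (length(keep) < 2) {
    stop("pruning would retain fewer than 2 tips (", length(keep), ")")
  }
  out <- ape::keep.tip(phy, keep)
  validate_ultrametric_tree(out)
}
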