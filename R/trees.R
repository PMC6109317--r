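#' Read a chronogram from a Newick file
#'
#' A chronogram is a rooted tree whose branch lengths are in time units
#' (My). Branch lengths are required. Ultrametricity (equal root-to-tip
#' path lengths) is checked within a relative tolerance; violations warn
#' rather than fail because trees produced by calibration tools are often
#' numerically slightly off. Operations that need node ages
#' ([collapse_at_age()]) enforce a stricter bound themselves.
#'
#' @param path Newick file path.
#' @param tol relative tolerance for the ultrametricity warning.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_chronogram(tree, tol = tol)
}

#' Validate a phylo object as a chronogram
#' @param tree a `phylo` object.
#' @param tol relative ultrametricity tolerance for the warning.
#' @return `tree`, invisibly validated.
#' @export
validate_chronogram <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels")
  if (ultrametric_error(tree) > tol) {
    warning("tree is not ultrametric (relative error ",
            format(ultrametric_error(tree), digits = 3), ")")
  }
  tree
}

#' Relative ultrametricity error of a tree
#'
#' Maximum deviation of root-to-tip path lengths from their maximum,
#' relative to that maximum (0 for an exactly ultrametric tree).
#'
#' @param tree a `phylo` object with branch lengths.
#' @return non-negative scalar.
#' @export
ultrametric_error <- function(tree) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  if (h == 0) return(0)
  (h - min(d)) / h
}

# Root-to-node path lengths for every node (tips first, then internals).
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  tr <- stats::reorder(tree, "postorder")
  # preorder = reversed postorder edge list
  for (k in rev(seq_len(nrow(tr$edge)))) {
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + tr$edge.length[k]
  }
  depth
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured back from the present: tips sit at age 0 and the root
#' at the tree height (in the tree's time units).
#'
#' @param tree a `phylo` chronogram.
#' @return numeric vector over node ids (tips `1..Ntip`, then internal
#'   nodes), in the same units as the branch lengths.
#' @export
node_ages <- function(tree) {
  depth <- node_depths(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Branch decomposition of a tree against an OTU table
#'
#' Computes, for every branch (edge) of the chronogram, the summed relative
#' abundance of its descendant tips in every sample: the `p_b` quantities
#' that Allen's entropy and weighted UniFrac are built from. Done in a
#' single postorder accumulation per table, O(edges x samples).
#'
#' @param table an [otu_table()] in relative mode whose OTU ids are tips of
#'   `tree` (OTUs with zero total abundance may be absent from the tree).
#' @param tree a `phylo` chronogram.
#' @return list with `lengths` (per-edge branch lengths) and `p` (edges x
#'   samples matrix of descendant-tip abundance).
#' @export
branch_abundance <- function(table, tree) {
  if (otu_mode(table) != "relative") stop("branch_abundance needs a relative table")
  present <- colnames(table)[colSums(table) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stop("OTUs with nonzero abundance missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  ntip <- ape::Ntip(tree)
  S <- nrow(table)
  node_p <- matrix(0, ntip + tree$Nnode, S)
  idx <- match(colnames(table), tree$tip.label)
  keep <- !is.na(idx)
  node_p[idx[keep], ] <- t(unclass(table)[, keep, drop = FALSE])
  tr <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    node_p[tr$edge[k, 1], ] <- node_p[tr$edge[k, 1], ] + node_p[tr$edge[k, 2], ]
  }
  p <- node_p[tr$edge[, 2], , drop = FALSE]
  rownames(p) <- NULL
  colnames(p) <- rownames(table)
  list(lengths = tr$edge.length, p = p, edge = tr$edge)
}

#' Host phylogeny with divergence times and proximity weights
#'
#' Wraps a host chronogram together with its pairwise divergence-time
#' matrix `T` (time since the two species' lineages split, i.e. the age of
#' their most recent common ancestor, in My) and the phylogenetic proximity
#' weights `W` with `w_ij = 1/T_ij` used by Moran's I. A flag switches the
#' distance to the patristic distance (2x the split age on an ultrametric
#' tree).
#'
#' @param tree a `phylo` chronogram over host species.
#' @param distance `"divergence"` (split age, default) or `"patristic"`.
#' @return object of class `host_phylogeny`: list with `tree`, `T`
#'   (divergence matrix), `W` (inverse-distance weights, zero diagonal).
#' @export
host_phylogeny <- function(tree, distance = c("divergence", "patristic")) {
  distance <- match.arg(distance)
  validate_chronogram(tree)
  D <- ape::cophenetic.phylo(tree)
  Tm <- if (distance == "divergence") D / 2 else D
  if (any(Tm[upper.tri(Tm)] <= 0)) {
    stop("zero divergence time between distinct species; W undefined")
  }
  W <- 1 / Tm
  diag(W) <- 0
  structure(list(tree = tree, T = Tm, W = W, distance = distance),
            class = "host_phylogeny")
}

#' @export
print.host_phylogeny <- function(x, ...) {
  cat(sprintf("host_phylogeny: %d species, root age %.1f, %s distance\n",
              ape::Ntip(x$tree), max(x$T), x$distance))
  invisible(x)
}
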