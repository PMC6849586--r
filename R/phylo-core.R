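#' Read a rooted phylogeny from Newick text or file
#'
#' Parses a rooted Newick tree with branch lengths and validates it for use
#' with the trait models in this package. Node heights are measured forward in
#' time from the root (root = 0, tips at the tree height for ultrametric
#' trees).
#'
#' @param source Newick string, or path to a file containing one tree.
#' @return An object of class `"phylo"` (from \pkg{ape}) with tip order equal
#'   to the left-to-right order in the Newick string.
#' @details Distinct conditions signal distinct error classes so callers can
#'   react programmatically: `burstshift_parse_error`,
#'   `burstshift_missing_branch_length`, `burstshift_negative_branch_length`,
#'   `burstshift_duplicate_tip`. Zero-length branches are accepted with a
#'   warning (they occur in published supertrees) but negative lengths are a
#'   hard error.
#' @examples
#' phy <- read_newick("((A:1,B:1):1,C:2);")
#' node_heights(phy)
#' @export
read_newick <- function(source) {
  txt <- source
  if (length(source) == 1L && !grepl("\\(", source) && file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop(errorCondition("malformed Newick string",
                        class = c("burstshift_parse_error", "error")))
  }
  validate_phylo(phy)
  phy
}

validate_phylo <- function(phy) {
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length)) {
    stop(errorCondition("every edge must carry a branch length",
                        class = c("burstshift_missing_branch_length", "error")))
  }
  if (any(phy$edge.length < 0)) {
    stop(errorCondition("negative branch lengths are not allowed",
                        class = c("burstshift_negative_branch_length", "error")))
  }
  if (anyDuplicated(phy$tip.label)) {
    stop(errorCondition(
      paste("duplicate tip labels:",
            paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", ")),
      class = c("burstshift_duplicate_tip", "error")))
  }
  if (any(phy$edge.length == 0)) {
    warning("tree contains zero-length branches")
  }
  invisible(phy)
}

#' Node heights measured from the root
#'
#' @param phy A `"phylo"` object.
#' @return Numeric vector over all nodes (tips `1..n`, then internal nodes in
#'   ape numbering) of distances from the root; the root has height 0.
#' @export
node_heights <- function(phy) {
  ape::node.depth.edgelength(phy)
}

#' Total height of a tree
#'
#' @param phy A `"phylo"` object.
#' @return Maximum root-to-tip distance.
#' @export
tree_height <- function(phy) {
  max(node_heights(phy)[seq_len(ape::Ntip(phy))])
}

#' Test ultrametricity at a relative tolerance
#'
#' A tree is treated as ultrametric when the spread of tip heights divided by
#' the tree height is below `tol`.
#'
#' @param phy A `"phylo"` object.
#' @param tol Relative tolerance (default `1e-6`).
#' @return Logical.
#' @export
is_ultrametric_rel <- function(phy, tol = 1e-6) {
  h <- node_heights(phy)[seq_len(ape::Ntip(phy))]
  H <- max(h)
  H > 0 && (max(h) - min(h)) / H <= tol
}

assert_ultrametric <- function(phy, what = "this model") {
  if (!is_ultrametric_rel(phy)) {
    stop(errorCondition(
      paste0(what, " requires an ultrametric tree (relative tolerance 1e-6)"),
      class = c("burstshift_not_ultrametric", "error")))
  }
  invisible(TRUE)
}

#' Phylogenetic variance-covariance matrix of shared times
#'
#' `V[i, j]` is the height (time from the root) of the most recent common
#' ancestor of tips `i` and `j`; `V[i, i]` is the height of tip `i`. Under
#' Brownian motion with rate \eqn{\sigma^2}, tip trait values are multivariate
#' normal with covariance \eqn{\sigma^2 V}.
#'
#' @param phy A `"phylo"` object.
#' @return Symmetric `n x n` matrix with dimnames equal to the tip labels.
#' @export
vcv_shared_time <- function(phy) {
  ape::vcv(phy)
}

#' Select a nested clade by its subtending (shift) node
#'
#' Builds the clade bookkeeping used by the nested models: the member tips,
#' the stem branch length (parent of the shift node to the shift node), and
#' the crown depth (shift node to its tips).
#'
#' @param phy A `"phylo"` object.
#' @param node Internal node number in ape numbering (`n+1` is the root).
#' @return An object of class `"clade_selection"`: list with `node`, `tips`
#'   (labels), `tip_idx`, `stem`, `crown_depth`, `node_height`.
#' @export
clade_selection <- function(phy, node) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  if (node <= n) stop("shift node must be internal, not a tip")
  if (node == root) stop("the root cannot be a shift node; fit the whole-tree model instead")
  if (node > n + phy$Nnode) stop("node number out of range")
  h <- node_heights(phy)
  tip_idx <- clade_tip_indices(phy, node)
  if (length(tip_idx) >= n) {
    stop("clade spanning the whole tree is not a nested clade")
  }
  parent <- phy$edge[phy$edge[, 2] == node, 1]
  stem <- phy$edge.length[phy$edge[, 2] == node]
  if (stem == 0) warning("zero-length stem branch for the selected clade")
  structure(list(
    node = node,
    tips = phy$tip.label[tip_idx],
    tip_idx = tip_idx,
    stem = stem,
    crown_depth = max(h[tip_idx]) - h[node],
    node_height = h[node]
  ), class = "clade_selection")
}

# tip indices descending from an internal node (iterative stack, no recursion)
clade_tip_indices <- function(phy, node) {
  n <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v) else stack <- c(stack, kids[[as.character(v)]])
  }
  sort(out)
}

#' Partition the shared-time matrix into background and clade parts
#'
#' Splits `V` into `V0` (time accrued on branches outside the nested clade)
#' and `Veb` (time accrued on the clade's branches, the stem included), so
#' that `V0 + Veb == V` entrywise. For a pair of tips both inside the clade,
#' `Veb` holds the stem length plus their shared time since the crown node,
#' and `V0` holds the constant background time down to the stem's origin; all
#' `Veb` entries involving a non-member tip are zero.
#'
#' @param phy A `"phylo"` object.
#' @param clade A `"clade_selection"`, or an internal node number.
#' @return List of class `"vcv_decomposition"` with matrices `V`, `V0`, `Veb`.
#' @examples
#' phy <- read_newick("((A:1,B:1):1,C:2);")
#' d <- clade_partition(phy, ape::getMRCA(phy, c("A", "B")))
#' stopifnot(all(d$V0 + d$Veb == d$V))
#' @export
clade_partition <- function(phy, clade) {
  if (!inherits(clade, "clade_selection")) clade <- clade_selection(phy, clade)
  V <- vcv_shared_time(phy)
  idx <- clade$tip_idx
  Veb <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  # crown-relative shared heights within the clade, then add the stem
  Hc <- V[idx, idx, drop = FALSE] - clade$node_height
  Veb[idx, idx] <- Hc + clade$stem
  structure(list(V = V, V0 = V - Veb, Veb = Veb), class = "vcv_decomposition")
}

#' Enumerate candidate shift nodes
#'
#' All internal non-root nodes whose descendant tip count is at least
#' `ceiling(min_frac * n)` and at least `min_tips`, but below `n`. Ordered by
#' descendant count (decreasing) then preorder index, so the result is
#' deterministic.
#'
#' @param phy A `"phylo"` object.
#' @param min_frac Minimum clade size as a fraction of the tip count
#'   (default 0.25).
#' @param min_tips Absolute minimum clade size (default 2).
#' @return Integer vector of node numbers; may be empty.
#' @export
candidate_nodes <- function(phy, min_frac = 0.25, min_tips = 2L) {
  stopifnot(min_frac > 0, min_frac < 1)
  n <- ape::Ntip(phy)
  root <- n + 1L
  counts <- tip_counts_per_node(phy)
  need <- max(ceiling(min_frac * n), min_tips)
  nodes <- setdiff(seq.int(n + 1L, n + phy$Nnode), root)
  nodes <- nodes[counts[nodes] >= need & counts[nodes] < n]
  if (!length(nodes)) return(integer(0))
  pre <- preorder_index(phy)
  nodes[order(-counts[nodes], pre[nodes])]
}

tip_counts_per_node <- function(phy) {
  n <- ape::Ntip(phy)
  counts <- numeric(n + phy$Nnode)
  counts[seq_len(n)] <- 1
  # postorder accumulation
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    counts[eo$edge[k, 1]] <- counts[eo$edge[k, 1]] + counts[eo$edge[k, 2]]
  }
  counts
}

preorder_index <- function(phy) {
  eo <- ape::reorder.phylo(phy, "cladewise")
  idx <- numeric(ape::Ntip(phy) + phy$Nnode)
  idx[ape::Ntip(phy) + 1L] <- 1
  pos <- 2
  for (k in seq_len(nrow(eo$edge))) {
    idx[eo$edge[k, 2]] <- pos
    pos <- pos + 1
  }
  idx
}

#' Rescale a tree to unit height
#'
#' Divides every branch length by the tree height so the root-to-tip distance
#' becomes 1. Simulation studies in this package work on unit-height trees so
#' rate and shape parameters are comparable across trees.
#'
#' @param phy A `"phylo"` object with positive height.
#' @return The rescaled `"phylo"`.
#' @export
scale_to_unit_height <- function(phy) {
  H <- tree_height(phy)
  if (H <= 0) stop("cannot rescale a zero-height tree")
  phy$edge.length <- phy$edge.length / H
  phy
}
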