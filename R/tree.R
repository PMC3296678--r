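#' Read a rooted species tree from a Newick file
#'
#' Leaf labels must be unique and non-empty; multifurcations are preserved.
#' Internal nodes without labels receive stable generated labels so that
#' branches can be named by their child node throughout the package.
#'
#' @param path Newick file containing a single rooted tree
#' @param outgroup optional leaf label to record as the designated outgroup
#' @return a `phylo` object with an `outgroup` attribute
#' @export
read_newick <- function(path, outgroup = NULL) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  species_tree(tr, outgroup)
}

#' Construct a species tree object
#'
#' @param tr a `phylo` object (rooted)
#' @param outgroup optional leaf label
#' @return `phylo` with attribute `outgroup`
#' @export
species_tree <- function(tr, outgroup = NULL) {
  # the Newick root is taken as the root; basal multifurcations are allowed
  if (any(is.na(tr$tip.label)) || any(!nzchar(tr$tip.label)))
    stop("tree has an unlabelled leaf")
  if (anyDuplicated(tr$tip.label))
    stop("tree leaf labels are not unique")
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label)) ||
      any(is.na(tr$node.label))) {
    lab <- tr$node.label %||% rep("", tr$Nnode)
    lab[is.na(lab)] <- ""
    fill <- !nzchar(lab)
    lab[fill] <- paste0("n", which(fill))
    tr$node.label <- lab
  }
  if (!is.null(outgroup) && !outgroup %in% tr$tip.label)
    stop("outgroup ", outgroup, " is not a leaf of the tree")
  attr(tr, "outgroup") <- outgroup
  tr
}

# label of a node id (tips then internals, ape numbering); vectorised
node_label <- function(tree, node) {
  c(tree$tip.label, tree$node.label)[node]
}

node_id <- function(tree, label) {
  n <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop("no node labelled ", label)
  n + j
}

root_id <- function(tree) length(tree$tip.label) + 1L

tree_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# tip ids below a node (including the node itself if a tip)
tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree_children(tree, v)
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  out
}

# MRCA node id of a set of tip labels
mrca_of <- function(tree, tips) {
  ids <- match(tips, tree$tip.label)
  stopifnot(!any(is.na(ids)))
  if (length(ids) == 1L) return(ids)
  ape::getMRCA(tree, ids)
}

# all edges strictly inside the subtree rooted at `node` plus the edge to it
edges_below <- function(tree, node) {
  keep <- logical(nrow(tree$edge))
  desc <- c(node, integer(0))
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    idx <- which(tree$edge[, 1] == v)
    keep[idx] <- TRUE
    kids <- tree$edge[idx, 2]
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  which(keep)
}
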