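#' Species-tree utilities
#'
#' Trees are `ape::phylo` objects, rooted, with unique leaf labels matching
#' genome-table species names. Branches are identified by the label of the
#' node (or leaf) below them; unlabeled internal nodes are auto-labelled
#' `n<number>` on load.
#'
#' @param x Newick string, file path, or a `phylo` object.
#' @export
read_species_tree <- function(x) {
  tree <- if (inherits(x, "phylo")) x
          else if (length(x) == 1 && file.exists(x)) ape::read.tree(x)
          else ape::read.tree(text = x)
  if (is.null(tree)) stop("read_species_tree: could not parse tree")
  if (!ape::is.rooted(tree)) stop("read_species_tree: tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("read_species_tree: duplicate leaf names")
  n <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- rep("", n)
  blank <- !nzchar(tree$node.label)
  tree$node.label[blank] <- paste0("n", which(blank) + length(tree$tip.label))
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

node_by_label <- function(tree, label) {
  i <- match(label, node_labels(tree))
  if (is.na(i)) stop("unknown tree node label '", label, "'")
  i
}

root_node <- function(tree) length(tree$tip.label) + 1L

tree_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# leaf labels under a node (node given as index)
clade_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree_children(tree, nd)
    out <- c(out, tree$tip.label[kids[kids <= ntip]])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

# most recent common ancestor of a set of leaf labels (node index)
mrca_node <- function(tree, leaves) {
  stopifnot(length(leaves) >= 1)
  tips <- match(leaves, tree$tip.label)
  if (anyNA(tips)) stop("mrca_node: unknown leaves ", paste(leaves[is.na(tips)], collapse = ", "))
  if (length(tips) == 1) return(tips[1])
  ape::getMRCA(tree, tips)
}

# nodes in preorder (parents before children), starting at the root
preorder_nodes <- function(tree) {
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  out <- integer(0)
  stack <- root_node(tree)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(tree_children(tree, nd), stack)
  }
  out
}

parent_node <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (!length(p)) NA_integer_ else p
}
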