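# Internal helpers for working with ape "phylo" trees.

# Postorder edge arrays and node naming shared by the parsimony and
# association code.  Node numbering follows ape: tips 1..n_tip, root
# n_tip + 1.
tree_index <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted")
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("node", seq_len(tree$Nnode) + n_tip)
  }
  list(
    tree = tree,
    edge_parent = tree$edge[, 1L],
    edge_child = tree$edge[, 2L],
    edge_length = if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge)) else tree$edge.length,
    n_tip = n_tip,
    n_node = n_node,
    node_names = c(tree$tip.label, internal)
  )
}

# Align a named tip-value vector to tip order; unnamed vectors must match
# the number of tips and are taken in tip-label order.
align_tip_values <- function(values, tix) {
  labs <- tix$tree$tip.label
  if (!is.numeric(values)) stop("tip values must be numeric")
  if (!is.null(names(values))) {
    miss <- setdiff(labs, names(values))
    if (length(miss)) {
      stop("tip values missing for: ", paste(miss, collapse = ", "))
    }
    values <- values[labs]
  } else if (length(values) != tix$n_tip) {
    stop("unnamed tip values must have one entry per tip")
  }
  unname(values)
}

# branch labels "parent->child" in postorder edge order
branch_labels <- function(tix) {
  paste0(tix$node_names[tix$edge_parent], "->", tix$node_names[tix$edge_child])
}

# round to nearest integer, exact halves toward the lower integer;
# used when resolving parsimony states to integer gene counts
round_half_down <- function(x) ceiling(x - 0.5)
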