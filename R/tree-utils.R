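# Small helpers over ape::phylo objects.

# Distance from the root to every node (tips first, then internal nodes).
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# MRCA of a set of tips (tip indices or labels); a single tip is its own MRCA.
mrca_of <- function(tree, tips) {
  if (is.character(tips)) tips <- match(tips, tree$tip.label)
  if (anyNA(tips)) stop("unknown tip label", call. = FALSE)
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}

# Tip indices descending from each internal node, as a list indexed by node id.
clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  desc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # postorder guarantees children are filled before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

# Children of a node.
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

# Length of the edge above a node (NA for the root).
stem_length <- function(tree, node) {
  i <- match(node, tree$edge[, 2L])
  if (is.na(i)) return(NA_real_)
  tree$edge.length[i]
}
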