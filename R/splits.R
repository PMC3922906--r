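# descendant tip labels per node (list indexed by node number)
node_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (v in seq_len(ntip)) sets[[v]] <- phy$tip.label[v]
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; c <- eo$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

# canonical key of one side of a bipartition: the side not containing the
# lexicographically smallest leaf, labels sorted and joined
split_key <- function(side, all_leaves) {
  ref <- min(all_leaves)
  if (ref %in% side) side <- setdiff(all_leaves, side)
  paste(sort(side), collapse = "\x1f")
}

# canonical keys of all non-trivial splits of a tree (treated as unrooted);
# named by the internal node whose parent edge induces the split
node_split_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  all_leaves <- phy$tip.label
  sets <- node_tip_sets(phy)
  root <- ntip + 1L
  nodes <- setdiff(root + seq_len(phy$Nnode) - 1L, root)
  keys <- vapply(nodes, function(v) {
    side <- sets[[v]]
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    split_key(side, all_leaves)
  }, character(1))
  names(keys) <- nodes
  keys[!is.na(keys)]
}

#' Non-trivial bipartitions of a tree
#'
#' One canonical bipartition per internal edge of the tree treated as
#' unrooted; pendant edges (and, for rooted binary storage, the duplicate
#' split at the root) are excluded. Each bipartition is represented by the
#' side not containing the lexicographically smallest leaf label.
#'
#' @param phy A `phylo` object.
#' @return A list of character vectors (sorted leaf labels of the canonical
#'   side); the full leaf set is attached as attribute `leaves`.
#' @export
bipartitions <- function(phy) {
  keys <- unique(node_split_keys(phy))
  out <- lapply(keys, function(k) strsplit(k, "\x1f", fixed = TRUE)[[1]])
  attr(out, "leaves") <- sort(phy$tip.label)
  out
}
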