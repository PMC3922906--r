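#' Test whether a leaf set is a clan of an unrooted tree
#'
#' A clan is a set of leaves separable from all others by cutting a single
#' edge of the tree treated as unrooted. Singletons are always clans
#' (pendant edge); the full leaf set is a clan by convention.
#'
#' @param phy A `phylo` tree (rooted storage is treated as unrooted).
#' @param leaves Character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_clan <- function(phy, leaves) {
  if (length(leaves) == 0) stop("empty leaf set")
  unknown <- setdiff(leaves, phy$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  leaves <- unique(leaves)
  n <- length(phy$tip.label)
  # singletons and their complements are separated by a pendant edge
  if (length(leaves) %in% c(1L, n - 1L, n)) return(TRUE)
  split_key(leaves, phy$tip.label) %in% node_split_keys(phy)
}

#' Clan status of every taxon rank on a tree
#'
#' For each rank present among the leaves, and for the merged class of all
#' plant ranks, reports whether its leaves form a clan of the unrooted
#' tree. The vertical-inheritance (monophyly) test passes when the
#' `nonplant` leaves form a single clan.
#'
#' @param phy A `phylo` tree.
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]).
#' @return Data.frame with columns `class`, `n_leaves`, `clan`.
#' @export
monophyly_report <- function(phy, taxonomy) {
  ranks <- leaf_ranks(phy$tip.label, taxonomy)
  classes <- intersect(ALL_RANKS, unique(ranks))
  rows <- lapply(classes, function(rk) {
    lv <- phy$tip.label[ranks == rk]
    data.frame(class = rk, n_leaves = length(lv), clan = is_clan(phy, lv))
  })
  plant <- phy$tip.label[ranks != "nonplant"]
  if (length(plant)) {
    rows <- c(rows, list(data.frame(class = "all_plant",
                                    n_leaves = length(plant),
                                    clan = is_clan(phy, plant))))
  }
  do.call(rbind, rows)
}

#' Root a tree on an outgroup clan
#'
#' Places the root on the edge separating the outgroup from the remaining
#' leaves, at `position` of that edge's length (measured from the outgroup
#' side). The total branch length is conserved. Errors if the outgroup is
#' not a clan (there is no silent fallback).
#'
#' @param phy A `phylo` tree (treated as unrooted).
#' @param outgroup Character vector of outgroup leaf labels (a proper
#'   subset of the leaves).
#' @param position Fraction of the separating edge allotted to the
#'   outgroup side (default: midpoint).
#' @return A rooted `phylo` tree.
#' @export
root_by_outgroup <- function(phy, outgroup, position = 0.5) {
  stopifnot(position >= 0, position <= 1)
  outgroup <- unique(outgroup)
  if (length(outgroup) >= length(phy$tip.label)) {
    stop("outgroup must be a proper subset of the leaves")
  }
  if (!is_clan(phy, outgroup)) {
    stop("outgroup is not a clan; cannot root")
  }
  phy <- ape::unroot(phy)
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  if (!is.null(rooted$node.label)) {      # ape labels the new root "Root"
    rooted$node.label[rooted$node.label == "Root"] <- ""
  }
  re <- which(rooted$edge[, 1] == root)
  if (length(re) == 2 && !is.null(rooted$edge.length)) {
    sets <- node_tip_sets(rooted)
    og_side <- vapply(rooted$edge[re, 2],
                      function(v) setequal(sets[[v]], outgroup), logical(1))
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re[og_side]] <- position * tot
    rooted$edge.length[re[!og_side]] <- (1 - position) * tot
  }
  rooted
}
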