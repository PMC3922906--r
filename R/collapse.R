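# recursive (nested-list) view of a phylo tree: each node is
# list(label, len, support, children); leaves have no children
tree_to_rlist <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- phy$edge.length
  eidx <- integer(ntip + phy$Nnode)
  eidx[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  sup <- tree_support(phy)
  rec <- function(v) {
    len <- if (!is.null(elen) && eidx[v] > 0L) elen[eidx[v]] else NA_real_
    if (v <= ntip) {
      return(list(label = phy$tip.label[v], len = len,
                  support = NA_real_, children = NULL))
    }
    list(label = NA_character_, len = len,
         support = unname(sup[as.character(v)]),
         children = lapply(kids[[as.character(v)]], rec))
  }
  rec(ntip + 1L)
}

rlist_to_newick <- function(node) {
  rec <- function(nd) {
    body <- if (is.null(nd$children)) {
      quote_label(nd$label)
    } else {
      paste0("(", paste(vapply(nd$children, rec, character(1)),
                        collapse = ","), ")",
             if (!is.na(nd$support)) format_num(nd$support) else "")
    }
    if (!is.na(nd$len)) paste0(body, ":", sprintf("%.15g", nd$len)) else body
  }
  paste0(rec(node), ";")
}

rlist_to_phylo <- function(node) read_newick(rlist_to_newick(node))

#' Collapse poorly supported internal edges into polytomies
#'
#' Every internal edge whose support is at most `threshold` is contracted
#' (its children are promoted to the grandparent); an edge is kept only when
#' its support is strictly greater than the threshold, matching the
#' "higher than 75%" reporting convention. Edges without a support value
#' (and pendant edges) are never contracted; the contracted edge's length is
#' dropped, leaving child branch lengths unchanged.
#'
#' @param phy A `phylo` tree with supports in `node.label`.
#' @param threshold Support threshold (fraction, default 0.75).
#' @return A `phylo` tree, possibly with polytomies.
#' @export
collapse_low_support <- function(phy, threshold = 0.75) {
  rt <- tree_to_rlist(phy)
  rec <- function(nd) {
    if (is.null(nd$children)) return(nd)
    newkids <- list()
    for (ch in nd$children) {
      ch <- rec(ch)
      if (!is.null(ch$children) && !is.na(ch$support) &&
          ch$support <= threshold) {
        newkids <- c(newkids, ch$children)   # promote grandchildren
      } else {
        newkids <- c(newkids, list(ch))
      }
    }
    nd$children <- newkids
    nd
  }
  rlist_to_phylo(rec(rt))
}
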