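#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration: at each step the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` (with `r` the row sums) is
#' joined; limb lengths follow the usual formulas. For determinism, exact
#' ties in `Q` are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by the smallest leaf it contains), and
#' negative limb lengths are clamped to zero with the deficit moved to the
#' sibling limb. The result is an unrooted tree stored with a basal
#' trifurcation (a single split for n = 2).
#'
#' @param D Symmetric labelled distance matrix (see [dist_matrix()]).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  check_dist_matrix(D)
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2) stop("neighbor joining needs at least 2 taxa")
  # per-cluster state: newick fragment and the smallest contained leaf label
  nwk <- setNames(as.list(labels), labels)
  key <- setNames(labels, labels)
  if (n == 2) {
    h <- D[1, 2] / 2
    txt <- sprintf("(%s:%.15g,%s:%.15g);", labels[1], h, labels[2], h)
    return(ape::read.tree(text = txt))
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted cluster-key pairs
    ck <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[[rownames(D)[ij[1]]]], key[[rownames(D)[ij[2]]]]))
      paste(ks, collapse = "\x1f")
    })
    pick <- cand[order(ck)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; if (li < 0) li <- 0 }
    ni <- rownames(D)[i]; nj <- rownames(D)[j]
    new_lab <- paste0("{", ni, "+", nj, "}")
    nwk[[new_lab]] <- sprintf("(%s:%.15g,%s:%.15g)", nwk[[ni]], li,
                              nwk[[nj]], lj)
    key[[new_lab]] <- min(key[[ni]], key[[nj]])
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_lab)
    D <- D2
  }
  a <- rownames(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 nwk[[a[1]]], lens[1], nwk[[a[2]]], lens[2],
                 nwk[[a[3]]], lens[3])
  ape::read.tree(text = txt)
}
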