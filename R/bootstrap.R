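#' Map split support from a set of trees onto a reference tree
#'
#' For each internal edge of the reference, support is the fraction of the
#' supplied trees whose bipartition set contains that edge's canonical
#' bipartition (exact matches only).
#'
#' @param reference A `phylo` tree.
#' @param trees List of `phylo` trees over the same leaf set.
#' @return The reference tree with supports (fractions) in `node.label`.
#' @export
support_from_trees <- function(reference, trees) {
  if (length(trees) == 0) stop("no trees to compute support from")
  ref_keys <- node_split_keys(reference)
  counts <- setNames(numeric(length(ref_keys)), names(ref_keys))
  for (tr in trees) {
    if (!setequal(tr$tip.label, reference$tip.label)) {
      stop("replicate tree leaf set differs from the reference")
    }
    tk <- unique(node_split_keys(tr))
    counts <- counts + (ref_keys %in% tk)
  }
  ntip <- length(reference$tip.label)
  sup <- rep(NA_real_, reference$Nnode)
  idx <- as.integer(names(ref_keys)) - ntip
  sup[idx] <- counts / length(trees)
  set_support(reference, sup)
}

#' Bootstrap split support for a tree
#'
#' Resamples alignment columns with replacement (one replicate per seed
#' substream derived from `(seed, replicate index)`), rebuilds distances and
#' a neighbor-joining tree per replicate, and maps the fraction of
#' replicates maintaining each reference split onto the reference tree.
#' Replicates in which some pair of sequences shares no sampled columns are
#' dropped with a warning and the support denominator decremented.
#'
#' @param aln Alignment object; ids must equal the reference leaf set.
#' @param reference `phylo` tree to annotate.
#' @param replicates Number of bootstrap replicates (published setting:
#'   1000).
#' @param seed Integer seed controlling all resampling.
#' @param model Distance model (see [model_distance()]).
#' @return The reference tree with fractional supports in `node.label`.
#' @export
bootstrap_support <- function(aln, reference, replicates = 1000L,
                              seed = 1L, model = "jtt_ml") {
  stopifnot(replicates >= 1)
  if (!setequal(names(aln), reference$tip.label)) {
    stop("alignment ids and reference leaf set differ")
  }
  L <- alignment_length(aln)
  m <- aln_matrix(aln)
  trees <- vector("list", replicates)
  kept <- 0L
  for (b in seq_len(replicates)) {
    set.seed((seed + b) %% .Machine$integer.max)
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- aln_from_matrix(m[, cols, drop = FALSE])
    tr <- tryCatch(neighbor_joining(dist_matrix(rep_aln, model)),
                   error = function(e) NULL)
    if (is.null(tr)) {
      warning("bootstrap replicate ", b,
              " dropped (undefined distances); denominator decremented")
      next
    }
    kept <- kept + 1L
    trees[[kept]] <- tr
  }
  if (kept == 0L) stop("all bootstrap replicates failed")
  support_from_trees(reference, trees[seq_len(kept)])
}
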