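# The fixed land-plant rank ladder:
#   (green_algae,(bryophyte,(lycophyte,(monocot,eudicot))))
# with internal nodes viridiplantae > embryophyte > vascular > angiosperm.
# Each node is encoded by its ancestor chain (self first, root last), which
# makes rank-ladder LCAs a chain intersection.
LADDER_CHAINS <- list(
  green_algae  = c("green_algae", "viridiplantae"),
  bryophyte    = c("bryophyte", "embryophyte", "viridiplantae"),
  lycophyte    = c("lycophyte", "vascular", "embryophyte", "viridiplantae"),
  monocot      = c("monocot", "angiosperm", "vascular", "embryophyte",
                   "viridiplantae"),
  eudicot      = c("eudicot", "angiosperm", "vascular", "embryophyte",
                   "viridiplantae"),
  angiosperm   = c("angiosperm", "vascular", "embryophyte", "viridiplantae"),
  vascular     = c("vascular", "embryophyte", "viridiplantae"),
  embryophyte  = c("embryophyte", "viridiplantae"),
  viridiplantae = "viridiplantae"
)

# lowest common ancestor of a set of ladder nodes
ladder_lca <- function(nodes) {
  nodes <- unique(nodes)
  chain <- LADDER_CHAINS[[nodes[1]]]
  for (nd in nodes[-1]) chain <- intersect(chain, LADDER_CHAINS[[nd]])
  chain[1]
}

# is ladder node a a strict ancestor of b?
ladder_above <- function(a, b) {
  a != b && a %in% LADDER_CHAINS[[b]]
}

#' Rank-level LCA mapping and duplication labelling of a rooted gene tree
#'
#' Maps every node of a rooted gene tree to the lowest rank-ladder node
#' containing all ranks of its descendant leaves (computed post-order).
#' A node is labelled a duplication when some child maps to the same ladder
#' node; otherwise it is a speciation. The rule applies unchanged at
#' polytomies. Nonplant leaves must be pruned beforehand.
#'
#' @param phy A rooted `phylo` tree.
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]).
#' @return Data.frame with one row per node (`node`, `mapping`, `event`);
#'   leaves carry event `"leaf"`.
#' @export
lca_map <- function(phy, taxonomy) {
  ranks <- leaf_ranks(phy$tip.label, taxonomy)
  if (any(ranks == "nonplant")) {
    stop("prune outgroup before classification: nonplant leaf(s) ",
         paste(phy$tip.label[ranks == "nonplant"], collapse = ", "))
  }
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  mapping <- character(nn)
  mapping[seq_len(ntip)] <- ranks
  event <- rep("leaf", nn)
  if (ntip > 1) {
    eo <- ape::reorder.phylo(phy, "postorder")
    kids <- split(eo$edge[, 2], eo$edge[, 1])
    done <- logical(nn)
    # postorder: each node's last parent-row comes after all its children
    for (k in seq_len(nrow(eo$edge))) {
      p <- eo$edge[k, 1]
      if (done[p]) next
      ch <- kids[[as.character(p)]]
      if (any(mapping[ch] == "")) next   # not all children ready yet
      mapping[p] <- ladder_lca(mapping[ch])
      event[p] <- if (any(mapping[ch] == mapping[p])) "duplication"
                  else "speciation"
      done[p] <- TRUE
    }
  } else {
    # degenerate single-leaf tree: the root inherits the leaf's rank
    mapping[ntip + 1L] <- ranks[1]
    event[ntip + 1L] <- "speciation"
  }
  data.frame(node = seq_len(nn), mapping = mapping, event = event)
}

# generic boundary traversal shared by group and supergroup detection:
# descend while the mapping is strictly above `boundary`, or while the node
# is a duplication mapping exactly to `boundary`; otherwise emit the node.
boundary_roots <- function(phy, ann, boundary, start = NULL) {
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  out <- integer(0)
  rec <- function(v) {
    m <- ann$mapping[v]
    ev <- ann$event[v]
    descend <- ladder_above(m, boundary) ||
      (m == boundary && ev == "duplication")
    if (descend && v > ntip) {
      for (ch in kids[[as.character(v)]]) rec(ch)
    } else {
      out[[length(out) + 1L]] <<- v
    }
  }
  rec(if (is.null(start)) ntip + 1L else start)
  out
}

#' Group roots of a reconciled gene tree
#'
#' A group is the set of family members descended from a single gene
#' present in the last common ancestor of monocots and eudicots. The
#' traversal descends from the root while the mapping is strictly above
#' `angiosperm`, or while an `angiosperm`-mapped node is a duplication
#' (it then spans two or more ancestral angiosperm genes); the first node
#' failing both tests is emitted as a group root. Emitted roots with no
#' angiosperm leaves are unplaced lineage-specific clades, not groups.
#'
#' @param phy Rooted `phylo` tree.
#' @param ann Annotations from [lca_map()].
#' @param start Node to start from (default: the root).
#' @return Integer vector of node numbers.
#' @export
find_group_roots <- function(phy, ann, start = NULL) {
  boundary_roots(phy, ann, "angiosperm", start)
}

#' Supergroup roots of a reconciled gene tree
#'
#' Same traversal as [find_group_roots()] with `embryophyte` as the
#' boundary: duplications mapping to `embryophyte` or `viridiplantae`
#' separate supergroups, while duplications mapping to `vascular` or
#' `angiosperm` create multiple groups within one supergroup.
#'
#' @inheritParams find_group_roots
#' @return Integer vector of node numbers.
#' @export
find_supergroup_roots <- function(phy, ann, start = NULL) {
  boundary_roots(phy, ann, "embryophyte", start)
}

# letters A, B, ..., Z, AA, AB, ... for supergroup naming
supergroup_letter <- function(i) {
  if (i <= 26) return(LETTERS[i])
  paste0(LETTERS[(i - 1) %/% 26], LETTERS[(i - 1) %% 26 + 1])
}

#' Classify a rooted gene tree into named supergroups and groups
#'
#' Runs the full reconciliation: optional collapse of poorly supported
#' edges, pruning of nonplant leaves, rank-level LCA mapping, supergroup
#' detection, then group detection within each supergroup subtree.
#' Supergroups are lettered `A, B, ...` in deterministic order (descending
#' leaf count, ties by lexicographically smallest contained leaf id);
#' groups take Roman numerals by the same order within each supergroup.
#' Each angiosperm leaf's half is `E` (eudicot) or `M` (monocot) by its own
#' rank; other plant leaves have half `none`. Clades emitted without
#' angiosperm leaves are reported as unplaced lineage-specific clades.
#'
#' @param phy Rooted `phylo` tree; if `collapse_threshold` is set its edges
#'   must carry support values.
#' @param taxonomy Taxonomy data.frame.
#' @param collapse_threshold Optional support threshold for
#'   [collapse_low_support()] applied before classification.
#' @return Object of class `famclade_classification`: a list with `leaves`
#'   (data.frame `leaf_id`, `supergroup`, `group`, `half`, `label`),
#'   `annotations`, `supergroup_roots`, `group_roots`, `unplaced` (list of
#'   character vectors) and the classified `tree`.
#' @export
classify <- function(phy, taxonomy, collapse_threshold = NULL) {
  if (!is.null(collapse_threshold)) {
    phy <- collapse_low_support(phy, collapse_threshold)
  }
  ranks <- leaf_ranks(phy$tip.label, taxonomy)
  drop <- phy$tip.label[ranks == "nonplant"]
  if (length(drop)) {
    if (length(drop) >= length(phy$tip.label) - 1) {
      stop("fewer than two plant leaves after pruning the outgroup")
    }
    phy <- ape::drop.tip(phy, drop)
  }
  ann <- lca_map(phy, taxonomy)
  ranks <- leaf_ranks(phy$tip.label, taxonomy)
  ntip <- length(phy$tip.label)
  sets <- node_tip_sets(phy)

  sg_nodes <- find_supergroup_roots(phy, ann)
  has_angio <- vapply(sg_nodes, function(v) {
    any(leaf_ranks(sets[[v]], taxonomy) %in% c("monocot", "eudicot"))
  }, logical(1))
  unplaced <- lapply(sg_nodes[!has_angio], function(v) sets[[v]])
  sg_nodes <- sg_nodes[has_angio]

  # deterministic naming order: descending leaf count, then smallest leaf id
  ord <- order(-lengths(sets[sg_nodes]),
               vapply(sets[sg_nodes], min, character(1)))
  sg_nodes <- sg_nodes[ord]

  leaves <- data.frame(leaf_id = phy$tip.label,
                       supergroup = NA_character_,
                       group = NA_character_,
                       half = ifelse(ranks == "eudicot", "E",
                                     ifelse(ranks == "monocot", "M", "none")),
                       label = NA_character_,
                       stringsAsFactors = FALSE)
  group_roots <- integer(0)
  for (i in seq_along(sg_nodes)) {
    letter <- supergroup_letter(i)
    sg_leaves <- sets[[sg_nodes[i]]]
    leaves$supergroup[leaves$leaf_id %in% sg_leaves] <- letter
    g_nodes <- find_group_roots(phy, ann, start = sg_nodes[i])
    g_angio <- vapply(g_nodes, function(v) {
      any(leaf_ranks(sets[[v]], taxonomy) %in% c("monocot", "eudicot"))
    }, logical(1))
    unplaced <- c(unplaced, lapply(g_nodes[!g_angio], function(v) sets[[v]]))
    g_nodes <- g_nodes[g_angio]
    gord <- order(-lengths(sets[g_nodes]),
                  vapply(sets[g_nodes], min, character(1)))
    g_nodes <- g_nodes[gord]
    for (j in seq_along(g_nodes)) {
      gl <- sets[[g_nodes[j]]]
      numeral <- as.character(as.roman(j))
      leaves$group[leaves$leaf_id %in% gl] <- numeral
    }
    group_roots <- c(group_roots, g_nodes)
  }
  placed <- !is.na(leaves$group)
  leaves$label[placed] <- paste0(leaves$supergroup[placed], "-",
                                 leaves$group[placed],
                                 ifelse(leaves$half[placed] == "none", "",
                                        paste0(" ", leaves$half[placed])))
  structure(list(leaves = leaves, annotations = ann,
                 supergroup_roots = sg_nodes, group_roots = group_roots,
                 unplaced = unplaced, tree = phy),
            class = "famclade_classification")
}

#' @export
print.famclade_classification <- function(x, ...) {
  ng <- length(x$group_roots)
  cat("Gene-family classification: ", length(x$supergroup_roots),
      " supergroup(s), ", ng, " group(s), ",
      sum(!is.na(x$leaves$group)), "/", nrow(x$leaves),
      " leaves placed\n", sep = "")
  if (length(x$unplaced)) {
    cat("Unplaced lineage-specific clades: ", length(x$unplaced), "\n",
        sep = "")
  }
  invisible(x)
}

#' Compare an inferred group partition with the simulated truth
#'
#' Compares the partitions of angiosperm leaves into groups. A merge is an
#' inferred group uniting two or more truth groups; a split is a truth
#' group broken across two or more inferred groups.
#'
#' @param classification A `famclade_classification`.
#' @param truth Data.frame with columns `leaf` and `true_group` (see
#'   [truth_from_history()]).
#' @return List with `exact_match`, `merges`, `splits`.
#' @export
compare_partitions <- function(classification, truth) {
  lv <- classification$leaves
  inf <- lv[lv$half %in% c("E", "M"), ]
  if (!setequal(inf$leaf_id, truth$leaf)) {
    stop("angiosperm leaf sets differ between inference and truth")
  }
  inf_grp <- setNames(paste(inf$supergroup, inf$group), inf$leaf_id)
  tru_grp <- setNames(as.character(truth$true_group), truth$leaf)
  ids <- inf$leaf_id
  tab <- table(inf_grp[ids], tru_grp[ids])
  merges <- sum(rowSums(tab > 0) >= 2)
  splits <- sum(colSums(tab > 0) >= 2)
  list(exact_match = merges == 0 && splits == 0,
       merges = merges, splits = splits)
}
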