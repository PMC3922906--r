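#' Read a Newick tree
#'
#' Parses standard Newick (via ape) with optional branch lengths and
#' support values in the internal-label position. Support values greater
#' than 1 are interpreted as percentages and divided by 100, so supports
#' are always stored as fractions in `[0, 1]` in `phy$node.label`.
#'
#' @param path Path to a Newick file (or a literal Newick string ending
#'   in `;`).
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  phy <- if (grepl(";", path, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = path),
             error = function(e) stop("failed to parse Newick: ",
                                      conditionMessage(e)))
  } else {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    tryCatch(ape::read.tree(path),
             error = function(e) stop("failed to parse Newick in ", path,
                                      ": ", conditionMessage(e)))
  }
  if (is.null(phy)) stop("failed to parse Newick (unbalanced parentheses?)")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  }
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0)) {
    stop("negative branch length in input tree")
  }
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    pct <- !is.na(sup) & sup > 1
    sup[pct] <- sup[pct] / 100
    phy$node.label <- ifelse(is.na(sup), "", format_num(sup))
    phy$node.label[is.na(sup)] <- ""
  }
  phy
}

# full-precision numeric formatting for Newick serialization
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a tree in Newick format
#'
#' Serializes branch lengths at full double precision (15 significant
#' digits) so `read_newick(write_newick(t))` preserves lengths to 1e-12,
#' and writes each edge's support value (a fraction) in the internal-label
#' position of its child node.
#'
#' @param phy A `phylo` object.
#' @param path Output path; if `NULL`, the Newick string is returned.
#' @return The path (invisibly) or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(phy, path = NULL) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- phy$edge.length
  eidx <- integer(ntip + phy$Nnode)          # node -> incoming edge row
  eidx[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  lab <- function(v) {
    if (v <= ntip) return(quote_label(phy$tip.label[v]))
    nl <- phy$node.label
    if (is.null(nl)) return("")
    quote_label(nl[v - ntip])
  }
  brl <- function(v) {
    if (is.null(elen) || eidx[v] == 0L) return("")
    paste0(":", sprintf("%.15g", elen[eidx[v]]))
  }
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(paste0(lab(v), brl(v)))
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           lab(v), brl(v))
  }
  root <- ntip + 1L
  txt <- paste0(rec(root), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

quote_label <- function(x) {
  if (!nzchar(x)) return(x)
  if (grepl("[ ():,;\\[\\]']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Per-edge support values of a tree
#'
#' @param phy A `phylo` object whose `node.label` holds fractional supports.
#' @return Numeric vector of length `phy$Nnode` (NA where absent), named by
#'   internal node number.
#' @export
tree_support <- function(phy) {
  n <- length(phy$tip.label)
  if (is.null(phy$node.label)) {
    return(setNames(rep(NA_real_, phy$Nnode), n + seq_len(phy$Nnode)))
  }
  setNames(suppressWarnings(as.numeric(phy$node.label)),
           n + seq_len(phy$Nnode))
}

# set supports (numeric fractions, NA allowed) onto node labels
set_support <- function(phy, sup) {
  stopifnot(length(sup) == phy$Nnode)
  lab <- format_num(sup)
  lab[is.na(sup)] <- ""
  phy$node.label <- lab
  phy
}
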