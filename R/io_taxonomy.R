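#' Read a species taxonomy table
#'
#' Tab-separated with header `abbrev<TAB>species<TAB>rank`. Ranks come from
#' the closed vocabulary `green_algae`, `bryophyte`, `lycophyte`, `monocot`,
#' `eudicot`, `nonplant`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `abbrev`, `species`, `rank`.
#' @export
read_taxonomy <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("abbrev", "species", "rank") %in% names(tab))) {
    stop("taxonomy table must have header 'abbrev\\tspecies\\trank'")
  }
  validate_taxonomy(tab[c("abbrev", "species", "rank")])
}

#' Validate a taxonomy table
#'
#' @param tab Data.frame with columns `abbrev`, `species`, `rank`.
#' @return The validated table (invisibly identical to the input).
#' @export
validate_taxonomy <- function(tab) {
  if (anyDuplicated(tab$abbrev)) {
    stop("duplicate species abbreviation(s): ",
         paste(unique(tab$abbrev[duplicated(tab$abbrev)]), collapse = ", "))
  }
  bad <- setdiff(unique(tab$rank), ALL_RANKS)
  if (length(bad)) {
    stop("unknown rank(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(ALL_RANKS, collapse = ", "), ")")
  }
  tab
}

#' Write a taxonomy table
#' @param tab Taxonomy data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tab, path) {
  write.table(validate_taxonomy(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Resolve the taxon rank of each leaf label
#'
#' Leaf labels carry the species abbreviation as a prefix in the field's
#' naming convention (`PtNRT2-A`, `MgAMT1-B`, `At_3`); the longest matching
#' abbreviation wins, so `Prp...` is never claimed by `Pt`.
#'
#' @param labels Character vector of leaf labels.
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]).
#' @return Named character vector of ranks, one per label.
#' @export
leaf_ranks <- function(labels, taxonomy) {
  validate_taxonomy(taxonomy)
  ab <- taxonomy$abbrev[order(nchar(taxonomy$abbrev), decreasing = TRUE)]
  rk <- setNames(taxonomy$rank, taxonomy$abbrev)
  out <- vapply(labels, function(lb) {
    for (a in ab) if (startsWith(lb, a)) return(rk[[a]])
    NA_character_
  }, character(1))
  if (anyNA(out)) {
    stop("leaf label(s) not mapping to any species abbreviation: ",
         paste(labels[is.na(out)], collapse = ", "))
  }
  out
}
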