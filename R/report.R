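RANK_REPORT_ORDER <- c("eudicot", "monocot", "lycophyte", "bryophyte",
                       "green_algae", "nonplant")

#' Family member-count table
#'
#' Cross-tabulates sequence assignments into a species-by-family count
#' table. Species rows follow the published layout order (eudicots, then
#' monocots, lycophytes, bryophytes, green algae), within rank in taxonomy
#' order; absent combinations count 0.
#'
#' @param assignments Data.frame with columns `seq_id`, `species_abbrev`,
#'   `family`.
#' @param taxonomy Taxonomy data.frame; every species appears as a row of
#'   the result even with zero members.
#' @return Data.frame with columns `abbrev`, `species`, `rank` and one
#'   integer column per family.
#' @export
count_table <- function(assignments, taxonomy) {
  validate_taxonomy(taxonomy)
  unknown <- setdiff(unique(assignments$species_abbrev), taxonomy$abbrev)
  if (length(unknown)) {
    stop("unknown species abbreviation(s): ", paste(unknown, collapse = ", "))
  }
  ord <- order(match(taxonomy$rank, RANK_REPORT_ORDER))
  tab <- taxonomy[ord, c("abbrev", "species", "rank")]
  rownames(tab) <- NULL
  fams <- sort(unique(assignments$family))
  for (fam in fams) {
    sub <- assignments[assignments$family == fam, ]
    cnt <- table(factor(sub$species_abbrev, levels = tab$abbrev))
    tab[[fam]] <- as.integer(cnt)
  }
  tab
}

#' Aggregate statistics over a member-count table
#'
#' @param table Count table from [count_table()] (or the packaged fixture,
#'   [table1_fixture()]).
#' @param family Name of the family column to aggregate.
#' @param ranks Optional character vector restricting to these ranks
#'   (default: all rows).
#' @param stat One of `"sum"`, `"mean_rounded"` (arithmetic mean rounded
#'   half-up to the nearest integer), `"min"`, `"max"`.
#' @return A single number.
#' @export
aggregate_counts <- function(table, family,
                             ranks = NULL,
                             stat = c("sum", "mean_rounded", "min", "max")) {
  stat <- match.arg(stat)
  if (!family %in% names(table)) stop("unknown family: ", family)
  rows <- if (is.null(ranks)) rep(TRUE, nrow(table)) else table$rank %in% ranks
  if (!any(rows)) stop("empty species selection")
  x <- table[[family]][rows]
  switch(stat,
         sum = sum(x),
         mean_rounded = floor(mean(x) + 0.5),
         min = min(x),
         max = max(x))
}

#' Packaged member-count fixture
#'
#' The published species-by-family table of analysed members (AMT1, AMT2,
#' NRT1/PTR, NRT2 across 20 land plants and 2 green algae), shipped as a
#' plain TSV so aggregate statistics can be recomputed offline.
#'
#' @return Count table data.frame (columns `abbrev`, `species`, `rank`,
#'   `AMT1`, `AMT2`, `NRT1/PTR`, `NRT2`).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_members.tsv", package = "famclade")
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
  validate_taxonomy(tab)
  tab
}

#' Write a member-count table as TSV
#' @param table Count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
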