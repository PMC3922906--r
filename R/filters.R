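#' Filtering configuration
#'
#' Thresholds for hit acceptance and alignment cleaning. Defaults follow the
#' published screen: at least 30% identity, E-value strictly lower than
#' 1e-50, hit coverage of at least half the query (the operational form of
#' the "no series of small fragments" rule), exclusion of sequences whose
#' gap fraction exceeds 30% of the alignment length, and removal of columns
#' whose similarity score is below 40%.
#'
#' @param min_identity_pct Minimum percent identity (accepted with `>=`).
#' @param max_evalue Maximum E-value (accepted with strict `<`).
#' @param min_hit_coverage Minimum hit length as a fraction of query length.
#' @param max_gap_fraction Gap fraction above which (strict `>`) a sequence
#'   is excluded.
#' @param min_column_score Column score below which (strict `<`) a column is
#'   dropped.
#' @param similarity_matrix Name of a Biostrings substitution matrix used by
#'   [column_scores()].
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_identity_pct = 30,
                          max_evalue = 1e-50,
                          min_hit_coverage = 0.5,
                          max_gap_fraction = 0.30,
                          min_column_score = 0.40,
                          similarity_matrix = "BLOSUM62") {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            max_evalue > 0,
            min_hit_coverage >= 0, min_hit_coverage <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_column_score >= 0, min_column_score <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 max_evalue = max_evalue,
                 min_hit_coverage = min_hit_coverage,
                 max_gap_fraction = max_gap_fraction,
                 min_column_score = min_column_score,
                 similarity_matrix = similarity_matrix),
            class = "filter_config")
}

#' Filter homology hits by identity, E-value and coverage
#'
#' A hit is accepted iff `pct_identity >= min_identity_pct` AND
#' `evalue < max_evalue` AND `aln_length >= min_hit_coverage * query_length`.
#' Each rejected hit carries the first failing test, in the order
#' `identity`, `evalue`, `coverage`.
#'
#' @param hits Hit data.frame (see [read_hits()]).
#' @param query_lengths Named integer vector of query sequence lengths.
#' @param cfg A [filter_config()].
#' @return List with elements `accepted` (data.frame) and `rejected`
#'   (data.frame with an extra `reason` column).
#' @export
filter_hits <- function(hits, query_lengths, cfg = filter_config()) {
  missing <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(missing)) {
    stop("no query length for: ", paste(missing, collapse = ", "))
  }
  if (nrow(hits) == 0) {
    rej <- hits
    rej$reason <- character(0)
    return(list(accepted = hits, rejected = rej))
  }
  qlen <- as.numeric(query_lengths[hits$query_id])
  fail_id <- hits$pct_identity < cfg$min_identity_pct
  fail_ev <- hits$evalue >= cfg$max_evalue
  fail_cov <- hits$aln_length < cfg$min_hit_coverage * qlen
  reason <- rep(NA_character_, nrow(hits))
  reason[fail_cov] <- "coverage"
  reason[fail_ev] <- "evalue"
  reason[fail_id] <- "identity"      # first failing test wins
  acc <- is.na(reason)
  rej <- hits[!acc, , drop = FALSE]
  rej$reason <- reason[!acc]
  list(accepted = hits[acc, , drop = FALSE], rejected = rej)
}

# per-row gap fraction of an alignment
gap_fractions <- function(aln) {
  m <- aln_matrix(aln)
  rowMeans(m == "-")
}

#' Exclude over-gapped sequences from an alignment
#'
#' A sequence is excluded iff its gap fraction strictly exceeds
#' `max_gap_fraction` ("large gaps exceeding more than 30% of the alignment
#' length"); a row with exactly the threshold fraction is kept.
#'
#' @param aln Alignment object.
#' @param cfg A [filter_config()].
#' @return List with `kept` (alignment, original order) and `excluded_ids`.
#' @export
gap_filter <- function(aln, cfg = filter_config()) {
  gf <- gap_fractions(aln)
  drop <- gf > cfg$max_gap_fraction
  if (all(drop)) stop("alignment emptied: all sequences exceed the gap limit")
  list(kept = as_alignment(unclass(aln)[!drop]),
       excluded_ids = names(aln)[drop])
}

# similarity matrix lookup (Biostrings data sets)
get_similarity_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Per-column similarity scores of a protein alignment
#'
#' For each column, the score is the fraction of unordered non-gap residue
#' pairs whose similarity-matrix entry is strictly positive. Columns with
#' fewer than two non-gap residues score 0. This is a transparent,
#' matrix-parameterised stand-in for aligner-internal local similarity
#' scores, thresholded identically (40% by default).
#'
#' @param aln Alignment object (at least 2 sequences).
#' @param cfg A [filter_config()]; `cfg$similarity_matrix` names the matrix.
#' @return Numeric vector of scores in `[0, 1]`, one per column.
#' @export
column_scores <- function(aln, cfg = filter_config()) {
  if (length(aln) < 2) stop("column_scores needs >= 2 sequences")
  m <- aln_matrix(aln)
  S <- get_similarity_matrix(cfg$similarity_matrix)
  known <- rownames(S)
  apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) < 2) return(0)
    res[!res %in% known] <- "X"      # unknown residues score via 'X' row
    pr <- utils::combn(res, 2)
    pos <- S[cbind(pr[1, ], pr[2, ])] > 0
    sum(pos) / length(pos)
  })
}

#' Trim low-scoring alignment columns
#'
#' Keeps exactly the columns whose [column_scores()] value is at least
#' `min_column_score` (a column scoring strictly below the threshold is
#' dropped, mirroring the "<40%" exclusion rule). Column order is preserved.
#'
#' @param aln Alignment object (at least 2 sequences).
#' @param cfg A [filter_config()].
#' @return List with `trimmed` (alignment) and `kept_columns` (0-based
#'   indices of retained columns).
#' @export
trim_columns <- function(aln, cfg = filter_config()) {
  sc <- column_scores(aln, cfg)
  keep <- sc >= cfg$min_column_score
  if (!any(keep)) stop("no alignment columns survive trimming")
  m <- aln_matrix(aln)[, keep, drop = FALSE]
  list(trimmed = aln_from_matrix(m), kept_columns = which(keep) - 1L)
}
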