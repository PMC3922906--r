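HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")
HIT_NUMERIC <- setdiff(HIT_COLUMNS, c("query_id", "subject_id"))

#' Read a 12-column tabular homology hit file
#'
#' The standard tab-separated search output (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' start/end, E-value, bit score). Lines starting with `#` are comments.
#'
#' @param path Path to the hit table.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, rows in file order.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  out <- as.data.frame(matrix(character(0), 0, 12,
                              dimnames = list(NULL, HIT_COLUMNS)))
  if (!any(keep)) {
    for (cc in HIT_NUMERIC) out[[cc]] <- numeric(0)
    return(out)
  }
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 12)) {
    bad <- which(keep)[which(nf != 12)[1]]
    stop("line ", bad, ": expected 12 tab-separated columns, found ",
         nf[which(nf != 12)[1]])
  }
  m <- do.call(rbind, rows)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- HIT_COLUMNS
  for (cc in HIT_NUMERIC) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      bad <- which(keep)[which(is.na(v))[1]]
      stop("line ", bad, ": unparseable number in column '", cc, "': ",
           out[[cc]][which(is.na(v))[1]])
    }
    out[[cc]] <- v
  }
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("pct_identity outside [0, 100]")
  }
  if (any(out$evalue < 0)) stop("negative evalue")
  if (any(out$aln_length < 1)) stop("aln_length must be >= 1")
  out$aln_length <- as.integer(out$aln_length)
  out
}

#' Write a hit table in 12-column tabular format
#'
#' Numeric pass-through columns are written so that [read_hits()] round-trips
#' them; integers print without decimals.
#'
#' @param hits Data.frame as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  fmt <- vapply(seq_len(nrow(hits)), function(i) {
    r <- hits[i, HIT_COLUMNS]
    vals <- vapply(r, function(x) {
      if (is.numeric(x)) format(x, scientific = NA, trim = TRUE, digits = 15)
      else as.character(x)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
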