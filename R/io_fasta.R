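#' Read protein sequences from a FASTA file
#'
#' Reads plain or aligned FASTA. The sequence identifier is the header token
#' up to the first whitespace; sequences are uppercased and the alternative
#' gap character `.` is normalised to `-`. `X` is treated as a residue, not
#' a gap.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are ids). An empty
#'   file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(character(0))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping; `Inf` writes one line per sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Assemble an alignment from equal-length sequences
#'
#' An alignment is represented as a named character vector with an
#' `famclade_alignment` class tag; all sequences must have identical length.
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @return The validated alignment object.
#' @export
as_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate ids in alignment")
  len <- unique(nchar(seqs))
  if (length(len) != 1) {
    stop("aligned sequences must have identical length; saw lengths ",
         paste(len, collapse = ", "))
  }
  if (len < 1) stop("alignment length must be >= 1")
  structure(seqs, class = "famclade_alignment")
}

#' @export
print.famclade_alignment <- function(x, ...) {
  cat("Alignment: ", length(x), " sequences x ", alignment_length(x),
      " columns\n", sep = "")
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln Alignment from [as_alignment()].
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) nchar(aln[[1]])

# alignment as a character matrix (rows = sequences, columns = positions)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

# rebuild an alignment object from a character matrix
aln_from_matrix <- function(m) {
  as_alignment(setNames(apply(m, 1, paste0, collapse = ""), rownames(m)))
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file.
#' @return An alignment object (see [as_alignment()]).
#' @export
read_alignment <- function(path) as_alignment(read_fasta(path))
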