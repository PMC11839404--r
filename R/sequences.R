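#' Construct a set of sequence records
#'
#' A sequence record set is the package's basic container for nucleotide
#' sequences: a plain `data.frame` with columns `id`, `desc`, and `residues`.
#' Residues may contain upper- or lowercase IUPAC nucleotide codes and `-`
#' gap characters; case is preserved throughout.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences (no whitespace).
#' @param desc optional character vector of descriptions (default `""`).
#' @return A `data.frame` with columns `id`, `desc`, `residues`.
#' @examples
#' seq_records(c("s1", "s2"), c("ACGT", "A-GT"))
#' @export
seq_records <- function(id, residues, desc = "") {
  id <- as.character(id)
  residues <- as.character(residues)
  desc <- rep_len(as.character(desc), length(id))
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length")
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(grepl("[[:space:]]", residues))) {
    stop("residues must not contain whitespace")
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  data.frame(id = id, desc = desc, residues = residues,
             stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' Wrapped sequence lines are concatenated; the text after the first
#' whitespace in a header is dropped from the id but kept in `desc`.
#' Gap characters and IUPAC ambiguity codes are accepted and case is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return sequence records (see [seq_records()]), in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(seq_records(character(), character())[0, , drop = FALSE])
  }
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seq_records(ids, as.character(set), desc)
}

#' Write sequence records to a FASTA file
#'
#' Output is deterministic: records in order, sequences wrapped at
#' `line_width` columns, gaps written as `-` verbatim (so aligned reads
#' keep their columns).
#'
#' @param records sequence records (see [seq_records()]).
#' @param path output path.
#' @param line_width sequence line width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  records <- validate_records(records)
  stopifnot(line_width >= 1)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Validate and normalize an alignment
#'
#' Checks that all residue strings in a record set have the same length
#' (at least one column) so the set can be used as a multiple sequence
#' alignment.
#'
#' @param records sequence records.
#' @return the records, unchanged, for piping.
#' @export
as_alignment <- function(records) {
  records <- validate_records(records)
  widths <- nchar(records$residues)
  if (nrow(records) == 0 || any(widths < 1)) {
    stop("an alignment needs at least one sequence with at least one column")
  }
  if (length(unique(widths)) != 1) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  }
  records
}

# Internal: coerce/validate a record set (data.frame with id/desc/residues).
validate_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "residues") %in% names(records))) {
    stop("expected a data.frame with columns 'id' and 'residues'")
  }
  if (is.null(records$desc)) records$desc <- ""
  records
}

# Character classes used by the damage model and filters.
GAP_CHAR <- "-"
UNAMBIG <- c("A", "C", "G", "T", "a", "c", "g", "t")

is_gap <- function(chars) chars == GAP_CHAR
is_unambig <- function(chars) chars %in% UNAMBIG
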