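## Protein sequence I/O and the tabular sequence representation.
##
## A sequence table has one row per record with columns:
##   id               character, FASTA header token before the first whitespace
##   residues         character, uppercase one-letter codes (X allowed)
##   length           integer
##   numbering_offset integer, residue number of the first character (1-based)

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA20, "X")
GAP_CHARS <- c("-", ".", "*")

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a tibble with one row per record.
#' Sequences are uppercased; the header token before the first whitespace
#' becomes the record id. Residue coordinates throughout the package are
#' 1-based inclusive, so the first residue of each record has coordinate
#' `numbering_offset` (1 unless overridden).
#'
#' Only the 20 standard one-letter amino-acid codes plus `X` (unknown residue,
#' which never matches any motif anchor) are accepted. Alignment gap symbols
#' (`-`, `.`, `*`) and ambiguity codes such as `B`/`Z`/`J` are rejected with a
#' message naming the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param numbering_offset Integer (default 1): residue number assigned to the
#'   first character of every record. Use e.g. 77 when the file holds a
#'   fragment that starts at residue 77 of the full-length protein.
#' @return A tibble with columns `id`, `residues`, `length`,
#'   `numbering_offset`.
#' @examples
#' fa <- system.file("extdata", "cav2_synthetic.fasta", package = "memphys")
#' read_fasta(fa)
#' @export
read_fasta <- function(path, numbering_offset = 1L) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate sequence id(s) in FASTA: ",
                 paste(dup, collapse = ", ")))
  }
  residues <- unname(toupper(as.character(set)))
  purrr::walk2(ids, residues, validate_residues)
  protein_table(ids, residues, numbering_offset)
}

#' Build a sequence table from residue strings
#'
#' @param id Character vector of sequence ids.
#' @param residues Character vector of one-letter residue strings (same
#'   length as `id`); lowercase input is uppercased.
#' @param numbering_offset Integer: coordinate of the first residue.
#' @return A tibble with columns `id`, `residues`, `length`,
#'   `numbering_offset`.
#' @examples
#' protein_table("frag", "FEISKYVMYKFL", numbering_offset = 77)
#' @export
protein_table <- function(id, residues, numbering_offset = 1L) {
  stopifnot(length(id) == length(residues))
  numbering_offset <- as.integer(numbering_offset)
  if (any(numbering_offset < 1L)) {
    abort("numbering_offset must be >= 1")
  }
  residues <- toupper(residues)
  purrr::walk2(id, residues, validate_residues)
  tibble(
    id = as.character(id),
    residues = residues,
    length = nchar(residues),
    numbering_offset = rep_len(numbering_offset, length(id))
  )
}

validate_residues <- function(id, residues) {
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) == 0L) {
    abort(paste0("record '", id, "' has an empty sequence"))
  }
  bad <- which(!chars %in% AA_ALLOWED)
  if (length(bad) > 0L) {
    pos <- bad[1]
    ch <- chars[pos]
    what <- if (ch %in% GAP_CHARS) {
      "alignment gap symbols are not allowed in sequence input"
    } else {
      "not a standard amino-acid code (20 letters plus X)"
    }
    abort(paste0("invalid residue '", ch, "' at position ", pos,
                 " of record '", id, "': ", what))
  }
  invisible(TRUE)
}
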