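## FASTA input/output: plain sequence sets, MSAs, and the two-record
## aligned-FASTA pair files produced by structural aligners.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20 standard
#' one-letter codes (plus X) is replaced by `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record identifiers
#'   (the first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  recs <- read_fasta_raw(path)
  ids <- names(recs)
  out <- vapply(seq_along(recs), function(i)
    sanitize_sequence(recs[[i]], ids[[i]], allow_gap = FALSE), character(1))
  names(out) <- ids
  out
}

## Shared FASTA reader: returns raw (unsanitized) named character vector,
## enforcing non-empty file and unique ids.
read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty identifier in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence for id '", ids[nchar(seqs) == 0L][1], "'")
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(names(seqs) != ""))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' Rows are uppercased, checked for equal length, and characters outside
#' the residue alphabet (plus gap and X) are replaced by `X` with a warning.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of gapped rows, class `"site_msa"`.
#' @export
read_msa <- function(path) {
  recs <- read_fasta_raw(path)
  ids <- names(recs)
  rows <- vapply(seq_along(recs), function(i)
    sanitize_sequence(recs[[i]], ids[[i]], allow_gap = TRUE), character(1))
  names(rows) <- ids
  as_msa(rows)
}

#' Construct an MSA object from gapped rows
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @return The rows with class `"site_msa"`.
#' @export
as_msa <- function(rows) {
  if (is.null(names(rows)) || any(names(rows) == ""))
    stop("MSA rows must be named by sequence id")
  if (anyDuplicated(names(rows)))
    stop("duplicate id(s) in MSA: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  if (length(unique(nchar(rows))) != 1L)
    stop("MSA rows have unequal lengths")
  structure(rows, class = "site_msa")
}

#' Read a pairwise alignment from a two-record aligned FASTA file
#'
#' The file must contain exactly two equal-length gapped records; the first
#' is taken as the reference row, the second as the target. Columns that are
#' gaps in both rows are removed.
#'
#' @param path Path to the aligned-FASTA pair file.
#' @return A `pairwise_alignment` object.
#' @export
read_pairwise_alignment_fasta <- function(path) {
  recs <- read_fasta_raw(path)
  if (length(recs) != 2L)
    stop("pairwise alignment file must contain exactly 2 records, found ",
         length(recs), ": ", path)
  ids <- names(recs)
  rows <- vapply(seq_along(recs), function(i)
    sanitize_sequence(recs[[i]], ids[[i]], allow_gap = TRUE), character(1))
  pairwise_alignment(ids[1], ids[2], rows[1], rows[2])
}

#' Construct a pairwise alignment
#'
#' Validates equal row lengths and removes columns gapped in both rows.
#'
#' @param ref_id,target_id Sequence identifiers.
#' @param ref_row,target_row Equal-length gapped rows.
#' @param score Optional alignment score to carry along.
#' @return List with fields `ref_id`, `target_id`, `ref_row`, `target_row`,
#'   class `"pairwise_alignment"`.
#' @export
pairwise_alignment <- function(ref_id, target_id, ref_row, target_row,
                               score = NULL) {
  if (nchar(ref_row) != nchar(target_row))
    stop("alignment rows have unequal lengths (", nchar(ref_row), " vs ",
         nchar(target_row), ") for '", ref_id, "' / '", target_id, "'")
  rc <- chars(ref_row); tc <- chars(target_row)
  both_gap <- rc == AA_GAP & tc == AA_GAP
  if (any(both_gap)) {
    rc <- rc[!both_gap]; tc <- tc[!both_gap]
    ref_row <- paste(rc, collapse = "")
    target_row <- paste(tc, collapse = "")
  }
  if (nchar(ref_row) == 0L) stop("alignment is empty after gap-column removal")
  structure(list(ref_id = unname(ref_id), target_id = unname(target_id),
                 ref_row = unname(ref_row), target_row = unname(target_row),
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment (", nchar(x$ref_row), " columns)\n", sep = "")
  cat(sprintf("  %-12s %s\n", x$ref_id, x$ref_row))
  cat(sprintf("  %-12s %s\n", x$target_id, x$target_row))
  if (!is.null(x$score)) cat("  score:", x$score, "\n")
  invisible(x)
}

## Extract the induced pairwise alignment of two MSA rows (drops columns
## gapped in both).
msa_pair <- function(msa, ref_id, target_id) {
  pairwise_alignment(ref_id, target_id, msa[[ref_id]], msa[[target_id]])
}
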