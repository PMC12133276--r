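## Mapping reference pocket positions through pairwise alignments (3D
## mode) or MSA columns (2D mode) to one fixed-length active-site string
## per family member.

#' Percent identity of a pairwise alignment
#'
#' Defined as 100 x matched columns / columns where both rows are non-gap.
#' Returns 0 when no column has both rows non-gap. Insensitive to terminal
#' gap padding by construction.
#'
#' @param alignment A `pairwise_alignment`.
#' @return Identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment) {
  rc <- chars(alignment$ref_row)
  tc <- chars(alignment$target_row)
  both <- rc != AA_GAP & tc != AA_GAP
  if (!any(both)) return(0)
  100 * sum(rc[both] == tc[both]) / sum(both)
}

#' Select the best reference for a target
#'
#' Given alignments of one target against several candidate references,
#' returns the reference with the highest percent identity (ties: first in
#' input order).
#'
#' @param target_alignments List of `pairwise_alignment` objects sharing
#'   the same target.
#' @return List with `reference_id`, `alignment`, and an identity `report`
#'   row (`member_id`, `reference_id`, `percent_identity`).
#' @export
select_reference <- function(target_alignments) {
  if (length(target_alignments) == 0L)
    stop("no alignments supplied for reference selection")
  ids <- vapply(target_alignments, `[[`, character(1), "ref_id")
  pid <- vapply(target_alignments, percent_identity, numeric(1))
  best <- which.max(pid)   # first maximum on ties
  aln <- target_alignments[[best]]
  list(reference_id = ids[best],
       alignment = aln,
       report = data.frame(member_id = aln$target_id,
                           reference_id = ids[best],
                           percent_identity = pid[best],
                           stringsAsFactors = FALSE))
}

#' Apply the reference-identity gate
#'
#' Members whose identity to their selected reference is below the
#' threshold are discarded (the gate is inclusive: identity equal to the
#' threshold passes). Clustering reliability degrades below roughly 30%
#' identity to the reference, hence the default.
#'
#' @param reports Data frame with columns `member_id`, `reference_id`,
#'   `percent_identity`.
#' @param threshold Identity threshold in `[0, 100]` (default 30).
#' @return List with `kept` (subset of `reports`) and `discarded`
#'   (data frame `id`, `reason`).
#' @export
apply_identity_gate <- function(reports, threshold = 30) {
  stopifnot(threshold >= 0, threshold <= 100)
  keep <- reports$percent_identity >= threshold
  discarded <- data.frame(id = reports$member_id[!keep],
                          reason = sprintf("identity<%s: %.1f",
                                           format(threshold),
                                           reports$percent_identity[!keep]),
                          stringsAsFactors = FALSE)
  list(kept = reports[keep, , drop = FALSE], discarded = discarded)
}

## Resolve pocket positions to 1-based indices in the reference sequence.
## With a structure, positions index the structure's ordered residue list
## (which must spell ref_sequence); without one, residue numbers are taken
## as sequence positions directly.
pocket_ref_indices <- function(pocket, ref_sequence, ref_structure = NULL) {
  if (!is.null(ref_structure)) {
    idx <- match_residues(ref_structure, pocket$chain, pocket$resno,
                          pocket$insert)
  } else {
    idx <- pocket$resno
  }
  if (any(idx < 1L | idx > nchar(ref_sequence)))
    stop("pocket position beyond the reference sequence (length ",
         nchar(ref_sequence), ")")
  idx
}

#' Active-site sequence container
#'
#' Site sets are plain data frames with columns `member_id`, `site`,
#' `reference_id`, `mode`; this constructor validates them.
#'
#' @param member_id,site,reference_id,mode Parallel vectors.
#' @return Data frame of class `c("active_sites", "data.frame")`.
#' @export
active_sites <- function(member_id, site, reference_id, mode) {
  stopifnot(all(mode %in% c("3d", "2d")))
  if (length(site) > 0L && length(unique(nchar(site))) != 1L)
    stop("site strings have unequal lengths")
  bad <- vapply(site, function(s) any(!(chars(s) %in% SITE_ALPHABET)),
                logical(1))
  if (any(bad))
    stop("site string for '", member_id[bad][1],
         "' contains characters outside the site alphabet")
  structure(data.frame(member_id = member_id, site = site,
                       reference_id = reference_id, mode = mode,
                       stringsAsFactors = FALSE),
            class = c("active_sites", "data.frame"))
}

#' Map pocket positions through a pairwise alignment (3D mode)
#'
#' For each pocket position, the alignment column carrying that reference
#' residue is located via the reference row, and the target row's character
#' at that column is emitted (`-` for a deletion in the target).
#'
#' @param alignment A `pairwise_alignment`; its degapped reference row must
#'   equal `ref_sequence`.
#' @param pocket A `pocket_definition`.
#' @param ref_sequence Reference polymer sequence.
#' @param ref_structure Optional `parsed_structure` used to resolve pocket
#'   author numbering to sequence positions.
#' @return One-row `active_sites` data frame, mode `"3d"`.
#' @export
map_pocket_through_alignment <- function(alignment, pocket, ref_sequence,
                                         ref_structure = NULL) {
  if (degap(alignment$ref_row) != ref_sequence)
    stop("degapped reference row does not match the reference sequence ",
         "for target '", alignment$target_id, "'")
  idx <- pocket_ref_indices(pocket, ref_sequence, ref_structure)
  rc <- chars(alignment$ref_row)
  cols <- which(rc != AA_GAP)[idx]   # alignment column of each ref residue
  site <- paste(chars(alignment$target_row)[cols], collapse = "")
  active_sites(alignment$target_id, site, alignment$ref_id, "3d")
}

#' Extract active sites from an MSA (2D mode)
#'
#' The reference row converts pocket positions to MSA columns; every other
#' row is read at those columns.
#'
#' @param msa A `site_msa` (named gapped rows).
#' @param reference_id Id of the reference row.
#' @param pocket A `pocket_definition`.
#' @param ref_sequence Optional; defaults to the degapped reference row.
#' @param ref_structure Optional structure for author-numbering resolution.
#' @return `active_sites` data frame over all non-reference rows, mode `"2d"`.
#' @export
extract_sites_from_msa <- function(msa, reference_id, pocket,
                                   ref_sequence = NULL,
                                   ref_structure = NULL) {
  if (!(reference_id %in% names(msa)))
    stop("reference id '", reference_id, "' not present in the MSA")
  ref_row <- msa[[reference_id]]
  if (is.null(ref_sequence)) ref_sequence <- degap(ref_row)
  if (degap(ref_row) != ref_sequence)
    stop("degapped MSA reference row does not match the reference sequence")
  idx <- pocket_ref_indices(pocket, ref_sequence, ref_structure)
  cols <- which(chars(ref_row) != AA_GAP)[idx]
  targets <- setdiff(names(msa), reference_id)
  sites <- vapply(targets, function(id)
    paste(chars(msa[[id]])[cols], collapse = ""), character(1))
  active_sites(targets, unname(sites), reference_id, "2d")
}

#' Discard sites with too many gaps
#'
#' Sites whose fraction of `-` characters exceeds `max_gap_fraction` are
#' discarded; each discard is recorded with its gap fraction.
#'
#' @param sites An `active_sites` data frame.
#' @param max_gap_fraction Highest tolerated gap fraction (default 0.5).
#' @return List with `kept` (`active_sites`) and `discarded` (data frame
#'   `id`, `reason`).
#' @export
apply_gap_discard <- function(sites, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  frac <- vapply(sites$site, function(s) mean(chars(s) == AA_GAP), numeric(1))
  keep <- frac <= max_gap_fraction
  list(kept = sites[keep, , drop = FALSE],
       discarded = data.frame(id = sites$member_id[!keep],
                              reason = sprintf("gap_fraction>%s: %.2f",
                                               format(max_gap_fraction),
                                               frac[!keep]),
                              stringsAsFactors = FALSE))
}
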