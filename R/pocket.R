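## Reference pocket definition: from P2RANK predictions, from ligand
## proximity in a holo structure, or from a user-supplied residue list.

#' Construct a pocket definition
#'
#' Positions are deduplicated and ordered ascending by
#' `(chain, residue_number, insertion_code)`; residue names are resolved
#' against the structure when one is given, otherwise against the reference
#' sequence (residue numbers then act as 1-based sequence positions).
#'
#' @param reference_id Identifier of the reference protein.
#' @param chain,resno,insert Parallel vectors of residue identifiers
#'   (author numbering).
#' @param structure Optional `parsed_structure` supplying residue names.
#' @param ref_sequence Optional reference sequence used when `structure`
#'   is absent.
#' @param source One of `"p2rank"`, `"ligand_proximity"`, `"user"`.
#' @return A `pocket_definition`: data frame with columns `chain`, `resno`,
#'   `insert`, `aa` plus attributes `reference_id` and `source`.
#' @export
pocket_definition <- function(reference_id, chain, resno, insert = NULL,
                              structure = NULL, ref_sequence = NULL,
                              source = "user") {
  if (length(resno) == 0L) stop("pocket must contain at least one residue")
  if (is.null(insert)) insert <- rep("", length(resno))
  df <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                   insert = as.character(insert), stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$chain, df$resno, df$insert), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(structure)) {
    idx <- match_residues(structure, df$chain, df$resno, df$insert)
    df$aa <- structure$residues$aa[idx]
  } else if (!is.null(ref_sequence)) {
    bad <- df$resno < 1L | df$resno > nchar(ref_sequence)
    if (any(bad))
      stop("pocket position ", df$chain[bad][1], "_", df$resno[bad][1],
           " is beyond the reference sequence (length ",
           nchar(ref_sequence), ")")
    df$aa <- chars(ref_sequence)[df$resno]
  } else {
    df$aa <- NA_character_
  }
  structure(df, class = c("pocket_definition", "data.frame"),
            reference_id = reference_id, source = source)
}

#' @export
print.pocket_definition <- function(x, ...) {
  cat("Pocket on '", attr(x, "reference_id"), "' (source: ",
      attr(x, "source"), "), ", nrow(x), " positions:\n", sep = "")
  cat(" ", paste0(x$chain, "_", x$resno, x$insert,
                  ifelse(is.na(x$aa), "", paste0("(", x$aa, ")")),
                  collapse = " "), "\n")
  invisible(x)
}

#' Parse a P2RANK predictions CSV
#'
#' Columns are matched case-insensitively after stripping spaces; the
#' expected columns are `name`, `score`, and `residue_ids` holding
#' space-separated `chain_resnum` tokens. Residues are resolved against
#' the structure; candidates are returned sorted by score, descending,
#' with ties kept in file order.
#'
#' @param csv_path Path to the predictions CSV.
#' @param structure A `parsed_structure` for the reference.
#' @return List of pocket candidates (`name`, `score`, `residues` data
#'   frame), class `"pocket_candidates"`.
#' @export
parse_p2rank_predictions <- function(csv_path, structure) {
  if (!file.exists(csv_path)) stop("P2RANK file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (nrow(df) == 0L) stop("empty P2RANK predictions file: ", csv_path)
  cn <- tolower(gsub("[[:space:]]", "", names(df)))
  need <- c("name", "score", "residue_ids")
  hit <- match(need, cn)
  if (anyNA(hit))
    stop("P2RANK file is missing column(s): ",
         paste(need[is.na(hit)], collapse = ", "))
  cands <- lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(trimws(df[[hit[3]]][i]), "[[:space:]]+")[[1]]
    toks <- toks[toks != ""]
    if (length(toks) == 0L)
      stop("pocket '", df[[hit[1]]][i], "' has no residues")
    parsed <- parse_residue_tokens(toks)
    match_residues(structure, parsed$chain, parsed$resno, parsed$insert)
    sc <- as.numeric(df[[hit[2]]][i])
    if (!is.finite(sc) || sc < 0)
      stop("pocket '", df[[hit[1]]][i], "' has invalid score")
    list(name = as.character(df[[hit[1]]][i]), score = sc, residues = parsed)
  })
  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "score"))]
  structure(cands, class = "pocket_candidates")
}

## "A_12" / "A_52B" -> (chain A, resno 12/52, insert ""/"B")
parse_residue_tokens <- function(tokens) {
  m <- regmatches(tokens,
                  regexec("^([^_]+)_([0-9]+)([A-Za-z]?)$", tokens))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable residue token: '", tokens[bad][1], "'")
  data.frame(chain = vapply(m, `[`, character(1), 2),
             resno = as.integer(vapply(m, `[`, character(1), 3)),
             insert = vapply(m, `[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Select a pocket candidate
#'
#' Without a rank, the highest-score candidate is returned; with
#' `rank = k`, the k-th best (1-based).
#'
#' @param candidates Result of [parse_p2rank_predictions()].
#' @param rank Optional 1-based rank by descending score.
#' @return A single pocket candidate.
#' @export
select_pocket <- function(candidates, rank = NULL) {
  if (length(candidates) == 0L) stop("no pocket candidates")
  if (is.null(rank)) rank <- 1L
  rank <- as.integer(rank)
  if (rank < 1L || rank > length(candidates))
    stop("pocket rank ", rank, " out of range (1..", length(candidates), ")")
  candidates[[rank]]
}

#' Detect the pocket from ligand proximity in a holo structure
#'
#' Keeps every polymer residue having at least one heavy atom within
#' `cutoff` of any heavy atom of the ligand. When `ligand_name` is absent
#' the HET group with the most heavy atoms is used (ties: first in file
#' order).
#'
#' @param structure A `parsed_structure` with at least one non-water HET
#'   group.
#' @param ligand_name Optional 3-letter HET residue name.
#' @param cutoff Contact distance in Angstrom (default 4.5, heavy atoms
#'   only).
#' @return A `pocket_definition` with source `"ligand_proximity"`.
#' @export
detect_pocket_by_ligand <- function(structure, ligand_name = NULL,
                                    cutoff = 4.5) {
  het <- structure$het_atoms
  het <- het[het$element != "H", , drop = FALSE]
  if (nrow(het) == 0L)
    stop("structure '", structure$id, "' has no non-water HET group; ",
         "supply the pocket residues explicitly")
  grp <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
  if (!is.null(ligand_name)) {
    het <- het[het$resid == ligand_name, , drop = FALSE]
    if (nrow(het) == 0L)
      stop("no HET group named '", ligand_name, "' in structure '",
           structure$id, "'")
    grp <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
  }
  sizes <- table(factor(grp, levels = unique(grp)))
  lig <- het[grp == names(sizes)[which.max(sizes)], , drop = FALSE]
  atoms <- structure$atoms
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  lx <- as.matrix(lig[, c("x", "y", "z")])
  ax <- as.matrix(atoms[, c("x", "y", "z")])
  ## squared distances atom-vs-ligand, min per polymer atom
  d2 <- outer(rowSums(ax^2), rep(1, nrow(lx))) +
    outer(rep(1, nrow(ax)), rowSums(lx^2)) - 2 * ax %*% t(lx)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  near <- mind <= cutoff
  if (!any(near))
    stop("no residue within ", cutoff, " Angstrom of ligand '",
         lig$resid[1], "'; supply the pocket residues explicitly")
  sel <- unique(atoms[near, c("chain", "resno", "insert")])
  pocket_definition(structure$id, sel$chain, sel$resno, sel$insert,
                    structure = structure, source = "ligand_proximity")
}

#' Build a pocket from a user-supplied residue list
#'
#' @param reference_id Reference identifier.
#' @param entries Character vector of `chain_resnum` tokens (insertion
#'   code appended to the number, e.g. `"A_52B"`).
#' @param structure Optional `parsed_structure` to resolve against.
#' @param ref_sequence Optional sequence (used when no structure is given;
#'   residue numbers are 1-based sequence positions).
#' @return A `pocket_definition` with source `"user"`.
#' @export
pocket_from_user_list <- function(reference_id, entries, structure = NULL,
                                  ref_sequence = NULL) {
  if (length(entries) == 0L) stop("empty pocket residue list")
  parsed <- parse_residue_tokens(entries)
  pocket_definition(reference_id, parsed$chain, parsed$resno, parsed$insert,
                    structure = structure, ref_sequence = ref_sequence,
                    source = "user")
}

#' Write / read a pocket definition as TSV
#'
#' Columns: `reference_id`, `chain`, `residue_number`, `insertion_code`,
#' `residue_name`.
#'
#' @param pocket A `pocket_definition`.
#' @param path TSV path.
#' @export
write_pocket_tsv <- function(pocket, path) {
  df <- data.frame(reference_id = attr(pocket, "reference_id"),
                   chain = pocket$chain,
                   residue_number = pocket$resno,
                   insertion_code = pocket$insert,
                   residue_name = ifelse(is.na(pocket$aa), "", pocket$aa),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_pocket_tsv
#' @param structure,ref_sequence Passed to [pocket_definition()] for
#'   re-resolution; when both are `NULL` the stored residue names are kept.
#' @export
read_pocket_tsv <- function(path, structure = NULL, ref_sequence = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(insertion_code = "character",
                                         chain = "character"))
  if (nrow(df) == 0L) stop("empty pocket file: ", path)
  df$insertion_code[is.na(df$insertion_code)] <- ""
  p <- pocket_definition(df$reference_id[1], df$chain, df$residue_number,
                         df$insertion_code, structure = structure,
                         ref_sequence = ref_sequence, source = "user")
  if (is.null(structure) && is.null(ref_sequence) &&
      "residue_name" %in% names(df)) {
    key <- paste(df$chain, df$residue_number, df$insertion_code, sep = "\r")
    p$aa <- df$residue_name[match(paste(p$chain, p$resno, p$insert,
                                        sep = "\r"), key)]
    p$aa[p$aa == ""] <- NA_character_
  }
  p
}
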