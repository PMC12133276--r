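## PDB structure input/output, built on bio3d. Only the information the
## pipeline needs is retained: ordered polymer residues with heavy-atom
## coordinates, and non-water HET groups.

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records via bio3d and returns a light-weight
#' structure object. Alternate locations other than blank or 'A' are
#' dropped so that a single conformer remains; water (HOH) is excluded from
#' the HET groups. Residue identity is `(chain, residue_number,
#' insertion_code)` in author numbering.
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return A `parsed_structure`: list with `id`, `chains`, `residues`
#'   (data frame: chain, resno, insert, resname, aa), `atoms` (polymer atom
#'   data frame) and `het_atoms` (non-water HETATM data frame).
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !any(at$type == "ATOM"))
    stop("no ATOM records in PDB file: ", path)
  ## single-conformer rule: keep altloc blank or 'A'
  alt <- at$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  at <- at[keep, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  element <- at$elesy
  noel <- element == ""
  ## fall back to first alphabetic character of the atom name
  element[noel] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                       gsub("^[0-9]+", "", at$elety[noel])), 1, 1))
  at$element <- element
  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    stop("non-finite coordinates in PDB file: ", path)
  cols <- c("type", "chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z")
  atoms <- at[at$type == "ATOM", cols, drop = FALSE]
  het <- at[at$type == "HETATM" & at$resid != "HOH", cols, drop = FALSE]
  rownames(atoms) <- NULL; rownames(het) <- NULL
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(key)
  residues <- data.frame(chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         insert = atoms$insert[first],
                         resname = atoms$resid[first],
                         aa = aa3to1(atoms$resid[first]),
                         stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(id = id,
                 chains = unique(atoms$chain),
                 residues = residues,
                 atoms = atoms,
                 het_atoms = het),
            class = "parsed_structure")
}

#' @export
print.parsed_structure <- function(x, ...) {
  cat("Structure '", x$id, "': ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " polymer atoms, ", nrow(x$het_atoms),
      " HET atoms (water excluded), chains: ",
      paste(x$chains, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' One-letter polymer sequence of a structure
#'
#' Residues are read in file order; non-standard residues appear as `X`.
#'
#' @param structure A `parsed_structure`.
#' @param chain Optional chain to restrict to.
#' @return Single sequence string.
#' @export
structure_sequence <- function(structure, chain = NULL) {
  res <- structure$residues
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  paste(res$aa, collapse = "")
}

#' Write a parsed structure to a PDB file
#'
#' Intended for the toy structures produced by [generate_toy_structure()];
#' coordinates survive a write/read round trip to the fixed-width PDB
#' precision (1e-3 Angstrom).
#'
#' @param structure A `parsed_structure`.
#' @param path Output path.
#' @export
write_pdb_structure <- function(structure, path) {
  all_at <- rbind(structure$atoms, structure$het_atoms)
  n <- nrow(all_at)
  if (n == 0L) stop("structure has no atoms")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(all_at[, c("x", "y", "z")]))),
                   type = all_at$type,
                   resno = all_at$resno,
                   resid = all_at$resid,
                   chain = all_at$chain,
                   insert = ifelse(all_at$insert == "", NA, all_at$insert),
                   eleno = seq_len(n),
                   elety = all_at$elety,
                   elesy = all_at$element,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

## Index of each pocket position within the structure's ordered residue
## list; errors name the first unresolved position.
match_residues <- function(structure, chain, resno, insert) {
  res <- structure$residues
  key <- paste(res$chain, res$resno, res$insert, sep = "\r")
  want <- paste(chain, resno, insert, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("residue ", chain[miss], "_", resno[miss], insert[miss],
         " not found in structure '", structure$id, "'")
  }
  idx
}
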