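## Residue alphabet shared across the package.
##
## Site strings are written over the 20 standard residues plus 'X' (unknown)
## and '-' (gap). All alignments use '-' as the gap character.

#' Standard amino-acid one-letter codes
#'
#' The 20 standard residues in alphabetical order. Site strings may
#' additionally contain `"X"` (unknown residue) and `"-"` (gap).
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_STANDARD
#' @export
AA_GAP <- "-"

#' @rdname AA_STANDARD
#' @export
AA_UNKNOWN <- "X"

## Full site alphabet: residues, gap, unknown.
SITE_ALPHABET <- c(AA_STANDARD, AA_GAP, AA_UNKNOWN)

#' Physicochemical residue classes
#'
#' Grouping of the 20 standard residues into six physicochemical classes:
#' aliphatic/hydrophobic (A, V, L, I, M), aromatic (F, W, Y), polar
#' (S, T, N, Q, C), basic (K, R, H), acidic (D, E) and conformationally
#' special (G, P). Residues within a class are treated as chemically
#' near-equivalent by the default distance matrix.
#'
#' @format Named list of character vectors.
#' @export
AA_CLASSES <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  aromatic  = c("F", "W", "Y"),
  polar     = c("S", "T", "N", "Q", "C"),
  basic     = c("K", "R", "H"),
  acidic    = c("D", "E"),
  special   = c("G", "P")
)

## residue -> class name lookup
aa_class_of <- function(aa) {
  map <- rep(names(AA_CLASSES), lengths(AA_CLASSES))
  names(map) <- unlist(AA_CLASSES, use.names = FALSE)
  unname(map[aa])
}

## Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## Convert 3-letter residue names to 1-letter codes; anything outside the
## standard table becomes 'X'.
aa3to1 <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[!(one %in% AA_STANDARD)] <- AA_UNKNOWN
  one
}

## Uppercase a sequence and replace characters outside the standard
## alphabet (+ X, and optionally the gap) by 'X', warning once per file.
sanitize_sequence <- function(seq, id, allow_gap = FALSE) {
  seq <- toupper(seq)
  allowed <- c(AA_STANDARD, AA_UNKNOWN, if (allow_gap) AA_GAP)
  cc <- chars(seq)
  bad <- !(cc %in% allowed)
  if (any(bad)) {
    warning(sprintf("sequence '%s': replaced %d non-standard character(s) (%s) by X",
                    id, sum(bad), paste(unique(cc[bad]), collapse = ",")),
            call. = FALSE)
    cc[bad] <- AA_UNKNOWN
    seq <- paste(cc, collapse = "")
  }
  seq
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)
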