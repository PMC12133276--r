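## The amino-acid distance matrix and the all-vs-all site score matrix.

#' Default amino-acid distance matrix
#'
#' A class-based distance over the 20 standard residues, the gap `-` and
#' the unknown residue `X`: identical symbols are at distance 0, residues
#' in the same physicochemical class (see [AA_CLASSES]) at 0.3, residues in
#' different classes at 1.0. A residue against a gap costs 1.0 and
#' `d("-","-") = 0`; `X` is at distance 0.5 from every other symbol
#' (unknown residues are mildly penalised, neither matches nor gaps).
#'
#' All entries lie in `[0, 1]`, the matrix is symmetric with a zero
#' diagonal, and it satisfies the triangle inequality. A custom matrix in
#' the same TSV layout can be substituted via [load_distance_matrix()].
#'
#' @param within_class Distance between distinct residues of the same
#'   class (default 0.3).
#' @param between_class Distance between residues of different classes,
#'   and residue-vs-gap (default 1.0).
#' @param unknown Distance of `X` to any other symbol (default 0.5).
#' @return Numeric 22x22 matrix with dimnames over the site alphabet,
#'   class `"aa_distance_matrix"`.
#' @export
default_distance_matrix <- function(within_class = 0.3, between_class = 1,
                                    unknown = 0.5) {
  ab <- SITE_ALPHABET
  m <- matrix(between_class, length(ab), length(ab), dimnames = list(ab, ab))
  cls <- aa_class_of(AA_STANDARD)
  for (i in seq_along(AA_STANDARD)) {
    same <- AA_STANDARD[cls == cls[i]]
    m[AA_STANDARD[i], same] <- within_class
  }
  m[AA_UNKNOWN, ] <- unknown
  m[, AA_UNKNOWN] <- unknown
  diag(m) <- 0
  validate_distance_matrix(m)
}

validate_distance_matrix <- function(m) {
  ab <- rownames(m)
  if (is.null(ab) || !identical(ab, colnames(m)))
    stop("distance matrix row and column labels differ")
  missing <- setdiff(c(AA_STANDARD, AA_GAP), ab)
  if (length(missing) > 0L)
    stop("distance matrix is missing symbol(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (any(m < 0 | m > 1))
    stop("distance matrix entries outside [0,1] (e.g. d(",
         ab[which(m < 0 | m > 1, arr.ind = TRUE)[1, 1]], ",...))")
  if (any(abs(diag(m)) > 1e-12)) {
    bad <- ab[which(abs(diag(m)) > 1e-12)[1]]
    stop("distance matrix diagonal is nonzero at '", bad, "'")
  }
  asym <- abs(m - t(m)) > 1e-9
  if (any(asym)) {
    ij <- which(asym, arr.ind = TRUE)[1, ]
    stop("distance matrix is asymmetric: d(", ab[ij[1]], ",", ab[ij[2]],
         ") != d(", ab[ij[2]], ",", ab[ij[1]], ")")
  }
  ## X handled by rule when absent from the file
  if (!(AA_UNKNOWN %in% ab)) {
    m2 <- matrix(0.5, nrow(m) + 1L, ncol(m) + 1L,
                 dimnames = list(c(ab, AA_UNKNOWN), c(ab, AA_UNKNOWN)))
    m2[ab, ab] <- m
    m2[AA_UNKNOWN, AA_UNKNOWN] <- 0
    m <- m2
  }
  structure(m, class = c("aa_distance_matrix", "matrix", "array"))
}

#' Load an amino-acid distance matrix from TSV
#'
#' The file must be a square, labelled, tab-separated table over the 20
#' residues plus `-` (and optionally `X`; when absent, `X` rows/columns
#' are filled by the 0.5-to-anything rule). All distance-matrix invariants
#' (symmetry, zero diagonal, entries in `[0,1]`) are validated and
#' violations are reported by name.
#'
#' @param path TSV path (row labels in the first column, column labels in
#'   the header).
#' @return An `aa_distance_matrix`.
#' @export
load_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("distance matrix file not found: ", path)
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("distance matrix file is not square")
  validate_distance_matrix(m)
}

#' Write a distance matrix to TSV
#'
#' @param m An `aa_distance_matrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(symbol = rownames(m), as.data.frame(unclass(m),
                   check.names = FALSE), check.names = FALSE)
  write_tsv(df, path)
}

#' Distance between two active-site strings
#'
#' The mean, over site positions, of the amino-acid distance between the
#' characters at that position. Because every matrix entry lies in
#' `[0, 1]`, so does the site distance — no rescaling is needed.
#'
#' @param s1,s2 Site strings of equal length.
#' @param m An `aa_distance_matrix` (default: [default_distance_matrix()]).
#' @return Distance in `[0, 1]`.
#' @export
site_distance <- function(s1, s2, m = default_distance_matrix()) {
  if (nchar(s1) != nchar(s2))
    stop("site strings have unequal lengths (", nchar(s1), " vs ",
         nchar(s2), ")")
  c1 <- chars(s1); c2 <- chars(s2)
  c1[!(c1 %in% rownames(m))] <- AA_UNKNOWN
  c2[!(c2 %in% rownames(m))] <- AA_UNKNOWN
  mean(m[cbind(c1, c2)])
}

#' All-vs-all active-site score matrix
#'
#' Symmetric n x n matrix of pairwise site distances with a zero diagonal
#' and all entries in `[0, 1]`.
#'
#' @param sites An `active_sites` data frame or a named character vector
#'   of equal-length site strings.
#' @param m An `aa_distance_matrix`.
#' @return Numeric matrix with member ids as dimnames, class
#'   `"score_matrix"`.
#' @export
build_score_matrix <- function(sites, m = default_distance_matrix()) {
  if (inherits(sites, "active_sites") || is.data.frame(sites)) {
    ids <- sites$member_id
    strs <- sites$site
  } else {
    ids <- names(sites)
    strs <- unname(sites)
  }
  n <- length(strs)
  if (n < 2L) stop("need at least 2 sites to build a score matrix")
  if (length(unique(nchar(strs))) != 1L)
    stop("site strings have unequal lengths")
  L <- nchar(strs[1])
  cm <- matrix(unlist(strsplit(strs, "", fixed = TRUE)), nrow = n,
               byrow = TRUE)
  cm[!(cm %in% rownames(m))] <- AA_UNKNOWN
  D <- matrix(0, n, n)
  for (k in seq_len(L)) D <- D + m[cm[, k], cm[, k]]
  D <- D / L
  D <- (D + t(D)) / 2          # exact symmetry despite float noise
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  structure(D, class = c("score_matrix", "matrix", "array"))
}

#' Write a score matrix to TSV
#'
#' @param score A `score_matrix`.
#' @param path Output path.
#' @export
write_score_matrix <- function(score, path) {
  df <- data.frame(member_id = rownames(score),
                   as.data.frame(unclass(score), check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}
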