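## Fallback global aligner (Needleman-Wunsch with affine gaps), used only
## when no structural alignment file is supplied for a target.

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch over the full lengths of both sequences. A gap run of
#' length g costs `gap_open + gap_extend * (g - 1)`, subtracted from the
#' substitution score total. The trace-back is deterministic: on score
#' ties, an aligned residue pair is preferred over a gap in the target row,
#' which is preferred over a gap in the reference row.
#'
#' @param seq_a Reference sequence (ungapped).
#' @param seq_b Target sequence (ungapped).
#' @param substitution Substitution matrix with residue dimnames; defaults
#'   to BLOSUM62 (from Biostrings).
#' @param gap_open,gap_extend Gap penalties (positive numbers; default
#'   10 / 0.5).
#' @param ref_id,target_id Identifiers stored in the result.
#' @return A `pairwise_alignment` whose `score` field holds the optimal
#'   global score.
#' @export
global_align <- function(seq_a, seq_b, substitution = NULL,
                         gap_open = 10, gap_extend = 0.5,
                         ref_id = "ref", target_id = "target") {
  stopifnot(nchar(seq_a) >= 1L, nchar(seq_b) >= 1L)
  if (is.null(substitution)) substitution <- blosum62()
  a <- chars(seq_a); b <- chars(seq_b)
  a[!(a %in% rownames(substitution))] <- "X"
  b[!(b %in% rownames(substitution))] <- "X"
  n <- length(a); m <- length(b)
  NEG <- -1e18
  ## state matrices: M aligned pair, GT gap in target row (consumes ref),
  ## GR gap in reference row (consumes target)
  M <- matrix(NEG, n + 1L, m + 1L)
  GT <- matrix(NEG, n + 1L, m + 1L)
  GR <- matrix(NEG, n + 1L, m + 1L)
  ## trace: 1 = from M, 2 = from GT, 3 = from GR
  tM <- matrix(0L, n + 1L, m + 1L)
  tGT <- matrix(0L, n + 1L, m + 1L)
  tGR <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    GT[i + 1L, 1L] <- -gap_open - gap_extend * (i - 1L)
    tGT[i + 1L, 1L] <- 2L
  }
  for (j in seq_len(m)) {
    GR[1L, j + 1L] <- -gap_open - gap_extend * (j - 1L)
    tGR[1L, j + 1L] <- 3L
  }
  sub <- substitution[a, b, drop = FALSE]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ## M(i,j): align a[i] with b[j]; tie preference M > GT > GR
      cand <- c(M[i, j], GT[i, j], GR[i, j])
      k <- which.max(cand)
      M[i + 1L, j + 1L] <- cand[k] + sub[i, j]
      tM[i + 1L, j + 1L] <- k
      ## GT(i,j): a[i] against '-', i.e. gap in target row
      cand <- c(M[i, j + 1L] - gap_open, GT[i, j + 1L] - gap_extend,
                GR[i, j + 1L] - gap_open)
      k <- which.max(cand)
      GT[i + 1L, j + 1L] <- cand[k]
      tGT[i + 1L, j + 1L] <- k
      ## GR(i,j): '-' against b[j], i.e. gap in reference row
      cand <- c(M[i + 1L, j] - gap_open, GT[i + 1L, j] - gap_open,
                GR[i + 1L, j] - gap_extend)
      k <- which.max(cand)
      GR[i + 1L, j + 1L] <- cand[k]
      tGR[i + 1L, j + 1L] <- k
    }
  }
  fin <- c(M[n + 1L, m + 1L], GT[n + 1L, m + 1L], GR[n + 1L, m + 1L])
  state <- which.max(fin)
  score <- fin[state]
  ## trace back
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      prev <- tM[i + 1L, j + 1L]
      ra <- c(a[i], ra); rb <- c(b[j], rb)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- tGT[i + 1L, j + 1L]
      ra <- c(a[i], ra); rb <- c("-", rb)
      i <- i - 1L
    } else {
      prev <- tGR[i + 1L, j + 1L]
      ra <- c("-", ra); rb <- c(b[j], rb)
      j <- j - 1L
    }
    state <- prev
  }
  pairwise_alignment(ref_id, target_id,
                     paste(ra, collapse = ""), paste(rb, collapse = ""),
                     score = score)
}

## BLOSUM62 from Biostrings, cached for the session.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
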