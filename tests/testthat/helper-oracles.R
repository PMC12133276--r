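## Independent brute-force oracles used to check the implementation.
## They share no code with the package paths they verify.

## --- DBSCAN oracle: explicit core enumeration + connected components ---
## Border points are attached to the adjacent component whose smallest
## core index is lowest (the component created first by an index-order
## scan).
brute_dbscan <- function(D, eps, min_samples) {
  n <- nrow(D)
  core <- which(vapply(seq_len(n), function(i) sum(D[i, ] <= eps),
                       numeric(1)) >= min_samples)
  labels <- rep(0L, n)
  if (length(core) > 0L) {
    ## connected components of core points under eps-reachability
    comp <- rep(NA_integer_, n)
    nc <- 0L
    for (s in core) {
      if (!is.na(comp[s])) next
      nc <- nc + 1L
      stack <- s
      while (length(stack) > 0L) {
        v <- stack[[1]]; stack <- stack[-1]
        if (!is.na(comp[v])) next
        comp[v] <- nc
        nbrs <- intersect(which(D[v, ] <= eps), core)
        stack <- c(stack, nbrs[is.na(comp[nbrs])])
      }
    }
    labels[core] <- comp[core]
    ## border points: non-core within eps of a core
    for (i in setdiff(seq_len(n), core)) {
      adj <- core[D[i, core] <= eps]
      if (length(adj) > 0L) {
        comps <- unique(comp[adj])
        firsts <- vapply(comps, function(cc)
          min(core[comp[core] == cc]), numeric(1))
        labels[i] <- comps[which.min(firsts)]
      }
    }
  }
  labels
}

## Canonical relabelling by first occurrence, noise (0) untouched, so two
## partitions can be compared exactly including border assignment.
canon_labels <- function(labels) {
  out <- integer(length(labels))
  seen <- integer(0)
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l == 0L) next
    k <- match(l, seen)
    if (is.na(k)) { seen <- c(seen, l); k <- length(seen) }
    out[i] <- k
  }
  out
}

## Random symmetric distance matrix in [0,1] with zero diagonal.
random_distance_matrix <- function(n) {
  D <- matrix(stats::runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("m", seq_len(n)), paste0("m", seq_len(n)))
  D
}

## --- pocket oracle: all-pairs heavy-atom distances, plain loops ---
brute_pocket_residues <- function(struct, cutoff, lig_atoms) {
  hits <- character(0)
  for (r in seq_len(nrow(struct$residues))) {
    res <- struct$residues[r, ]
    at <- struct$atoms[struct$atoms$chain == res$chain &
                       struct$atoms$resno == res$resno &
                       struct$atoms$insert == res$insert &
                       struct$atoms$element != "H", , drop = FALSE]
    found <- FALSE
    for (a in seq_len(nrow(at))) {
      for (l in seq_len(nrow(lig_atoms))) {
        d <- sqrt((at$x[a] - lig_atoms$x[l])^2 +
                  (at$y[a] - lig_atoms$y[l])^2 +
                  (at$z[a] - lig_atoms$z[l])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found)
      hits <- c(hits, paste(res$chain, res$resno, res$insert, sep = "_"))
  }
  sort(hits)
}

## Random toy structure: residues with 1-3 atoms at random coordinates,
## one multi-atom ligand.
random_toy_structure <- function(n_res) {
  rows <- list()
  for (r in seq_len(n_res)) {
    for (a in seq_len(sample(1:3, 1))) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "ATOM", chain = "A", resno = r, insert = "", resid = "ALA",
        elety = paste0("C", a), element = "C",
        x = stats::runif(1, 0, 30), y = stats::runif(1, 0, 30),
        z = stats::runif(1, 0, 30), stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  het <- data.frame(type = "HETATM", chain = "A",
                    resno = n_res + 1L, insert = "", resid = "LIG",
                    elety = paste0("C", 1:3), element = "C",
                    x = stats::runif(3, 5, 25), y = stats::runif(3, 5, 25),
                    z = stats::runif(3, 5, 25), stringsAsFactors = FALSE)
  residues <- unique(atoms[, c("chain", "resno", "insert", "resid")])
  residues$resname <- residues$resid
  residues$aa <- "A"
  structure(list(id = "rand", chains = "A",
                 residues = residues[, c("chain", "resno", "insert",
                                         "resname", "aa")],
                 atoms = atoms, het_atoms = het),
            class = "parsed_structure")
}

## --- aligner oracle: exhaustive enumeration of all global alignments ---
## Gap run of length g costs open + ext*(g-1); same convention as the
## implementation, but the optimum is found by enumerating every monotone
## alignment path.
enum_align_score <- function(a, b, sub, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, acc); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, "D", acc + sub[a[i], b[j]])
    if (i <= length(a))
      rec(i + 1, j, "U", acc - if (last == "U") ext else open)
    if (j <= length(b))
      rec(i, j + 1, "L", acc - if (last == "L") ext else open)
  }
  rec(1L, 1L, "", 0)
  best
}

## ARI with DBSCAN noise points treated as singleton clusters.
ari_vs_truth <- function(clustering, truth) {
  lab <- clustering$labels
  noise <- lab == 0L
  if (any(noise)) lab[noise] <- max(lab) + seq_len(sum(noise))
  mclust::adjustedRandIndex(lab, truth[clustering$member_ids])
}

## Random site strings over the full site alphabet.
random_sites <- function(n, L, p_gap = 0.1, p_x = 0.05) {
  probs <- c(rep((1 - p_gap - p_x) / 20, 20), p_gap, p_x)
  vapply(seq_len(n), function(i)
    paste(sample(c(AA_STANDARD, "-", "X"), L, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

## Minimal fixed-width PDB writer for hand-built records in tests.
pdb_line <- function(type = "ATOM", serial, name, alt = "", resname,
                     chain, resno, icode = "", x, y, z, element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resname, chain, resno, icode,
          x, y, z, 1, 0, element)
}
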