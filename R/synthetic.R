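## Synthetic enzyme families with planted isofunctional groups, plus toy
## helical structures with a placed ligand. Every pipeline stage can be
## exercised from these fixtures without any external data.

#' Specification of a synthetic enzyme family
#'
#' Group signatures share a common scaffold signature and differ at
#' `n_distinct` randomly chosen site positions, where each group receives
#' a residue from a different physicochemical class — so between-group
#' site distances are large under the default distance matrix, while
#' within-group noise substitutions are drawn from the same class and stay
#' near. A distinguished noise-free reference member (`reference_id`)
#' carries group 1's signature.
#'
#' @param n_groups Number of planted groups (<= 6, one physicochemical
#'   class per group at distinguishing positions).
#' @param members_per_group Members per group.
#' @param site_length Number of pocket positions.
#' @param seq_length Full sequence length (>= `site_length + 2`).
#' @param n_distinct Number of positions at which group signatures differ
#'   across classes (default 3).
#' @param p_noise Per-position probability of a same-class substitution
#'   (default 0.05).
#' @param p_gap Per-position probability of a gap (default 0.02).
#' @param p_scaffold Per-position scaffold divergence: probability that a
#'   member's non-site position differs from the family base scaffold by a
#'   uniform random residue (default 0.2, giving members roughly 80%
#'   full-length identity to the reference — a homologous family well
#'   above the default identity gate).
#' @param seed Integer seed; mandatory, every draw is reproducible.
#' @param reference_id Id of the reference member (default `"REF"`).
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_groups, members_per_group, site_length,
                        seq_length, n_distinct = 3, p_noise = 0.05,
                        p_gap = 0.02, p_scaffold = 0.2, seed,
                        reference_id = "REF") {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required for family generation")
  stopifnot(n_groups >= 1, members_per_group >= 1, site_length >= 1,
            p_noise >= 0, p_noise < 1, p_gap >= 0, p_gap < 1,
            p_scaffold >= 0, p_scaffold < 1,
            n_distinct >= 1, n_distinct <= site_length)
  if (n_groups > length(AA_CLASSES))
    stop("at most ", length(AA_CLASSES),
         " groups supported (one physicochemical class per group)")
  if (seq_length < site_length + 2L)
    stop("seq_length too small to embed a site of length ", site_length)
  structure(list(n_groups = as.integer(n_groups),
                 members_per_group = as.integer(members_per_group),
                 site_length = as.integer(site_length),
                 seq_length = as.integer(seq_length),
                 n_distinct = as.integer(n_distinct),
                 p_noise = p_noise, p_gap = p_gap,
                 p_scaffold = p_scaffold,
                 seed = as.integer(seed),
                 reference_id = reference_id),
            class = "family_spec")
}

#' Generate a synthetic enzyme family
#'
#' Each member's full sequence embeds its (noised, possibly gapped) group
#' signature at fixed scaffold offsets; non-site positions start from a
#' family base scaffold (uniform over the 20 residues) and diverge per
#' member at rate `p_scaffold`. The MSA has one column per scaffold
#' position (no insertion columns), so the member pairwise alignments
#' against the reference are exactly the MSA-induced pairs — 2D and 3D
#' extraction agree by construction. Identical seeds give identical
#' output.
#'
#' @param spec A [family_spec()].
#' @return List with `sequences` (named, ungapped), `true_labels` (named
#'   integer; reference = group 1), `true_sites` (named site strings),
#'   `msa` (`site_msa`), `alignments` (list of `pairwise_alignment`, one
#'   per non-reference member), `pocket` (`pocket_definition` on the
#'   reference), `site_positions` (1-based reference sequence positions),
#'   `reference_id`, and `spec`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, generate_family_impl(spec))
}

generate_family_impl <- function(spec) {
  L <- spec$site_length
  N <- spec$seq_length
  ## site columns spread across the scaffold at fixed offsets
  site_pos <- unique(round(seq(2, N - 1, length.out = L)))
  stopifnot(length(site_pos) == L)
  ## distinguishing positions and per-group cross-class residues
  dist_pos <- sort(sample(L, spec$n_distinct))
  base_sig <- sample(AA_STANDARD, L, replace = TRUE)
  class_order <- sample(names(AA_CLASSES), spec$n_groups)
  signatures <- matrix(rep(base_sig, spec$n_groups), nrow = spec$n_groups,
                       byrow = TRUE)
  for (p in dist_pos)
    for (g in seq_len(spec$n_groups))
      signatures[g, p] <- sample(AA_CLASSES[[class_order[g]]], 1)
  same_class_swap <- function(aa) {
    pool <- setdiff(AA_CLASSES[[aa_class_of(aa)]], aa)
    sample(pool, 1)
  }
  family_scaffold <- sample(AA_STANDARD, N, replace = TRUE)
  ids <- character(0); labels <- integer(0); sites <- character(0)
  rows <- character(0); seqs <- character(0)
  add_member <- function(id, group, noise, gap) {
    s <- signatures[group, ]
    if (noise > 0) {
      hit <- stats::runif(L) < noise
      s[hit] <- vapply(s[hit], same_class_swap, character(1))
    }
    if (gap > 0) s[stats::runif(L) < gap] <- AA_GAP
    scaffold <- family_scaffold
    div <- stats::runif(N) < spec$p_scaffold
    scaffold[div] <- sample(AA_STANDARD, sum(div), replace = TRUE)
    row <- scaffold
    row[site_pos] <- s
    ids <<- c(ids, id); labels <<- c(labels, group)
    sites <<- c(sites, paste(s, collapse = ""))
    rows <<- c(rows, paste(row, collapse = ""))
    seqs <<- c(seqs, degap(paste(row, collapse = "")))
  }
  add_member(spec$reference_id, 1L, 0, 0)    # clean reference, group 1
  for (g in seq_len(spec$n_groups))
    for (k in seq_len(spec$members_per_group))
      add_member(sprintf("G%d_M%02d", g, k), g, spec$p_noise, spec$p_gap)
  names(labels) <- ids; names(sites) <- ids
  names(rows) <- ids; names(seqs) <- ids
  msa <- as_msa(rows)
  alignments <- lapply(setdiff(ids, spec$reference_id), function(id)
    msa_pair(msa, spec$reference_id, id))
  names(alignments) <- setdiff(ids, spec$reference_id)
  pocket <- pocket_definition(spec$reference_id, chain = rep("A", L),
                              resno = site_pos,
                              ref_sequence = seqs[[spec$reference_id]],
                              source = "user")
  list(sequences = seqs, true_labels = labels, true_sites = sites,
       msa = msa, alignments = alignments, pocket = pocket,
       site_positions = site_pos, reference_id = spec$reference_id,
       spec = spec)
}

#' Generate a toy helical structure with a placed ligand
#'
#' Residues are placed on an ideal helix (rise 1.5 Angstrom, 100 degree
#' twist, radius 2.3 Angstrom) with one CA and one CB atom each; a single
#' HETATM ligand atom (`LIG`) is placed at the centroid of the designated
#' site residues' CA atoms, displaced along x by `ligand_offset`.
#'
#' @param sequence Residue sequence of the toy protein.
#' @param site_residue_indices 1-based residue indices defining the site.
#' @param ligand_offset Displacement of the ligand from the site centroid,
#'   in Angstrom (default 0).
#' @return A `parsed_structure` (chain A, residues numbered from 1),
#'   writable with [write_pdb_structure()].
#' @export
generate_toy_structure <- function(sequence, site_residue_indices,
                                   ligand_offset = 0) {
  n <- nchar(sequence)
  stopifnot(all(site_residue_indices >= 1),
            all(site_residue_indices <= n))
  aa <- chars(sequence)
  resid3 <- vapply(aa, function(a) {
    hit <- bio3d::aa123(a)
    if (is.na(hit)) "UNK" else hit
  }, character(1))
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  z <- (seq_len(n) - 1) * 1.5
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), z)
  cb <- cbind(3.8 * cos(theta), 3.8 * sin(theta), z)
  atoms <- data.frame(
    type = "ATOM",
    chain = "A",
    resno = rep(seq_len(n), each = 2L),
    insert = "",
    resid = rep(resid3, each = 2L),
    elety = rep(c("CA", "CB"), n),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    stringsAsFactors = FALSE)
  centroid <- colMeans(ca[site_residue_indices, , drop = FALSE])
  het <- data.frame(type = "HETATM", chain = "A", resno = n + 1L,
                    insert = "", resid = "LIG", elety = "C1",
                    element = "C",
                    x = centroid[1] + ligand_offset,
                    y = centroid[2], z = centroid[3],
                    stringsAsFactors = FALSE)
  residues <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                         resname = resid3, aa = aa3to1(resid3),
                         stringsAsFactors = FALSE)
  structure(list(id = "toy", chains = "A", residues = residues,
                 atoms = atoms, het_atoms = het),
            class = "parsed_structure")
}

#' Write a synthetic family as a fixture directory
#'
#' Writes `family.fasta` (full sequences), `msa.fasta`, one aligned-FASTA
#' pair per member under `alignments/`, `pocket.tsv`, `reference.fasta`
#' and `true_labels.tsv` into `dir`.
#'
#' @param fam Result of [generate_family()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_family_fixture <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fam$sequences, file.path(dir, "family.fasta"))
  write_fasta(unclass(fam$msa), file.path(dir, "msa.fasta"))
  write_fasta(fam$sequences[fam$reference_id],
              file.path(dir, "reference.fasta"))
  adir <- file.path(dir, "alignments")
  dir.create(adir, showWarnings = FALSE)
  for (aln in fam$alignments) {
    rows <- stats::setNames(c(aln$ref_row, aln$target_row),
                            c(aln$ref_id, aln$target_id))
    write_fasta(rows, file.path(adir, paste0(aln$target_id, ".fasta")))
  }
  write_pocket_tsv(fam$pocket, file.path(dir, "pocket.tsv"))
  write_tsv(data.frame(member_id = names(fam$true_labels),
                       group = unname(fam$true_labels)),
            file.path(dir, "true_labels.tsv"))
  invisible(dir)
}
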