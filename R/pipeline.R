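## Single entry point tying the stages together. Five run modes mirror
## the ways a family can be presented: detect the pocket on a reference
## structure (detect-pocket), supply a known pocket (known-pocket), start
## from user 3D models plus pairwise alignments (from-models), re-cluster
## a previous result (recluster), or start from an MSA (from-msa). A
## sixth mode, simulate, writes a synthetic fixture directory.

#' Build a validated run configuration
#'
#' Options may come from a YAML file, from the argument list, or both;
#' explicitly passed arguments override the YAML. Required inputs are
#' validated per mode before any computation starts.
#'
#' @param mode One of `"detect-pocket"`, `"known-pocket"`, `"from-models"`,
#'   `"recluster"`, `"from-msa"`, `"simulate"`.
#' @param config_yaml Optional YAML file holding any of the other options.
#' @param ref Reference PDB path (modes detect-pocket/known-pocket; also
#'   used in from-msa when pocket numbering must be resolved against a
#'   structure).
#' @param ref_fasta Optional FASTA with the reference sequence (from-msa).
#' @param pocket Pocket TSV path (known-pocket, from-models, from-msa).
#' @param p2rank P2RANK predictions CSV (detect-pocket).
#' @param pocket_rank 1-based rank among P2RANK candidates.
#' @param ligand Ligand residue name for proximity detection.
#' @param cutoff Ligand contact cutoff in Angstrom (default 4.5).
#' @param models Directory of target PDB models (from-models).
#' @param alignments Directory of aligned-FASTA pair files.
#' @param msa MSA FASTA path (from-msa).
#' @param reference_id Reference row id (from-msa; defaults to the pocket's
#'   reference id).
#' @param sequences Optional FASTA of full-length member sequences (for
#'   per-cluster FASTA output).
#' @param sites Sites TSV from a previous run (recluster).
#' @param groups Groups TSV from a previous run (recluster).
#' @param recluster_label Cluster number to subdivide (recluster).
#' @param matrix Optional distance-matrix TSV; default matrix otherwise.
#' @param id_threshold Reference identity gate in percent (default 30).
#' @param max_gap_fraction Gap-discard threshold (default 0.5).
#' @param eps,min_samples Optional explicit DBSCAN parameters; both absent
#'   triggers automatic selection.
#' @param outdir Output directory (required).
#' @param seed Integer seed (simulate mode).
#' @param n_groups,members_per_group,site_length,seq_length,n_distinct,p_noise,p_gap
#'   Family parameters (simulate mode).
#' @param render_logos Render PNG logos (default FALSE).
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode, config_yaml = NULL, ref = NULL,
                       ref_fasta = NULL, pocket = NULL, p2rank = NULL,
                       pocket_rank = NULL, ligand = NULL, cutoff = 4.5,
                       models = NULL, alignments = NULL, msa = NULL,
                       reference_id = NULL, sequences = NULL, sites = NULL,
                       groups = NULL, recluster_label = NULL,
                       matrix = NULL, id_threshold = 30,
                       max_gap_fraction = 0.5, eps = NULL,
                       min_samples = NULL, outdir = NULL, seed = NULL,
                       n_groups = 5, members_per_group = 40,
                       site_length = 12, seq_length = 60, n_distinct = 3,
                       p_noise = 0.05, p_gap = 0.02,
                       render_logos = FALSE) {
  cfg <- as.list(environment())
  cfg$config_yaml <- NULL
  if (!is.null(config_yaml)) {
    if (!file.exists(config_yaml)) stop("config file not found: ", config_yaml)
    yml <- yaml::read_yaml(config_yaml)
    given <- names(as.list(match.call()))[-1]
    for (k in setdiff(names(yml), c(given, "config_yaml")))
      if (k %in% names(cfg)) cfg[[k]] <- yml[[k]]
  }
  modes <- c("detect-pocket", "known-pocket", "from-models", "recluster",
             "from-msa", "simulate")
  if (length(cfg$mode) != 1L || !(cfg$mode %in% modes))
    stop("mode must be exactly one of: ", paste(modes, collapse = ", "))
  if (is.null(cfg$outdir)) stop("an output directory (outdir) is required")
  need <- function(field, what) {
    if (is.null(cfg[[field]]))
      stop("mode '", cfg$mode, "' requires ", what, " (", field, ")")
    if (field %in% c("ref", "pocket", "p2rank", "msa", "sites", "groups",
                     "sequences", "ref_fasta") && !file.exists(cfg[[field]]))
      stop(what, " not found: ", cfg[[field]])
    if (field %in% c("models", "alignments") && !dir.exists(cfg[[field]]))
      stop(what, " directory not found: ", cfg[[field]])
  }
  switch(cfg$mode,
    "detect-pocket" = need("ref", "a reference PDB"),
    "known-pocket" = { need("ref", "a reference PDB")
                       need("pocket", "a pocket TSV") },
    "from-models" = { need("pocket", "a pocket TSV")
                      need("models", "a models directory") },
    "from-msa" = { need("msa", "an MSA FASTA")
                   need("pocket", "a pocket TSV") },
    "recluster" = { need("groups", "a groups TSV from a previous run")
                    if (is.null(cfg$recluster_label))
                      stop("mode 'recluster' requires recluster_label") },
    "simulate" = { if (is.null(cfg$seed))
                     stop("mode 'simulate' requires a seed") })
  if (xor(is.null(cfg$eps), is.null(cfg$min_samples)))
    stop("supply both eps and min_samples, or neither (automatic)")
  stopifnot(cfg$id_threshold >= 0, cfg$id_threshold <= 100,
            cfg$max_gap_fraction >= 0, cfg$max_gap_fraction <= 1)
  structure(cfg, class = "run_config")
}

#' Run the pipeline
#'
#' Executes the configured mode and writes `groups.tsv`, per-cluster FASTA
#' files (when sequences are available), `summary.tsv` plus per-cluster
#' frequency matrices, `sites.tsv`, `discarded.tsv` and
#' `run_metadata.yaml` into the output directory. Partial outputs are
#' removed if a stage fails. Every input member is accounted for:
#' clustered + unclustered + discarded = inputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the `clustering` result, `sites`,
#'   `score` matrix, `discarded` data frame and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  fresh <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character(0)
  on.exit({
    if (!ok) {
      unlink(written, recursive = TRUE)
      if (fresh) unlink(outdir, recursive = TRUE)
    }
  })
  out <- function(...) {
    p <- file.path(outdir, ...)
    written <<- union(written, p)
    p
  }
  if (config$mode == "simulate") {
    spec <- family_spec(config$n_groups, config$members_per_group,
                        config$site_length, config$seq_length,
                        n_distinct = config$n_distinct,
                        p_noise = config$p_noise, p_gap = config$p_gap,
                        seed = config$seed)
    fam <- generate_family(spec)
    written <- union(written, outdir)
    write_family_fixture(fam, outdir)
    ok <- TRUE
    return(invisible(list(family = fam, outdir = outdir)))
  }
  m <- if (is.null(config$matrix)) default_distance_matrix()
       else load_distance_matrix(config$matrix)
  discarded <- data.frame(id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  sequences <- if (!is.null(config$sequences)) read_fasta(config$sequences)
  notes <- list()

  if (config$mode == "recluster") {
    prev <- read_groups_tsv(config$groups)
    sites <- active_sites(prev$member_id, prev$site, prev$reference_id,
                          rep("2d", nrow(prev)))
    lab <- as.integer(config$recluster_label)
    if (!(lab %in% prev$cluster) || lab == 0L)
      stop("cluster label ", lab, " not present in ", config$groups)
    keep <- prev$cluster == lab
    sites <- sites[keep, , drop = FALSE]
    score <- build_score_matrix(sites, m)
    params <- resolve_params(config, score)
    clustering <- dbscan_sites(score, params$eps, params$min_samples,
                               auto = params$auto)
  } else {
    ex <- extract_stage(config, notes)
    sites <- ex$sites; discarded <- ex$discarded; notes <- ex$notes
    gd <- apply_gap_discard(sites, config$max_gap_fraction)
    sites <- gd$kept
    discarded <- rbind(discarded, gd$discarded)
    if (nrow(sites) < 2L)
      stop("fewer than 2 members remain after filtering; nothing to cluster")
    score <- build_score_matrix(sites, m)
    params <- resolve_params(config, score)
    clustering <- dbscan_sites(score, params$eps, params$min_samples,
                               auto = params$auto)
  }

  write_sites_tsv(sites, out("sites.tsv"))
  write_groups_tsv(clustering, sites, out("groups.tsv"))
  write_discard_log(discarded, out("discarded.tsv"))
  written <- union(written, out("clusters"))
  write_cluster_report(clustering, sites, score, out("clusters"),
                       render_logos = isTRUE(config$render_logos))
  if (!is.null(sequences))
    write_cluster_fastas(clustering, sequences, out("clusters"))
  meta <- list(tool = "siteclust",
               version = as.character(utils::packageVersion("siteclust")),
               mode = config$mode,
               eps = clustering$params$eps,
               min_samples = clustering$params$min_samples,
               auto_params = clustering$params$auto,
               id_threshold = config$id_threshold,
               max_gap_fraction = config$max_gap_fraction,
               n_input = nrow(sites) + nrow(discarded),
               n_clustered = sum(clustering$labels != 0L),
               n_unclustered = sum(clustering$labels == 0L),
               n_discarded = nrow(discarded),
               notes = notes,
               input_checksums = input_checksums(config))
  yaml::write_yaml(meta, out("run_metadata.yaml"))
  ok <- TRUE
  invisible(list(clustering = clustering, sites = sites, score = score,
                 discarded = discarded, outdir = outdir))
}

resolve_params <- function(config, score) {
  if (!is.null(config$eps))
    list(eps = config$eps, min_samples = config$min_samples, auto = FALSE)
  else auto_params(score)
}

input_checksums <- function(config) {
  fields <- c("ref", "ref_fasta", "pocket", "p2rank", "msa", "sites",
              "groups", "sequences", "matrix")
  paths <- unlist(config[fields])
  paths <- paths[!is.null(paths) & file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

## Pocket definition + site extraction for the non-recluster modes.
extract_stage <- function(config, notes) {
  mode <- config$mode
  ref_structure <- NULL
  if (!is.null(config$ref)) ref_structure <- read_pdb(config$ref)
  if (mode == "detect-pocket") {
    pocket <- if (!is.null(config$p2rank)) {
      cand <- parse_p2rank_predictions(config$p2rank, ref_structure)
      best <- select_pocket(cand, rank = config$pocket_rank)
      pocket_definition(ref_structure$id, best$residues$chain,
                        best$residues$resno, best$residues$insert,
                        structure = ref_structure, source = "p2rank")
    } else {
      detect_pocket_by_ligand(ref_structure, ligand_name = config$ligand,
                              cutoff = config$cutoff)
    }
  } else {
    pocket <- read_pocket_tsv(config$pocket, structure = ref_structure)
  }
  ref_id <- if (!is.null(config$reference_id)) config$reference_id
            else attr(pocket, "reference_id")
  ref_sequence <-
    if (!is.null(config$ref_fasta)) {
      seqs <- read_fasta(config$ref_fasta)
      if (ref_id %in% names(seqs)) unname(seqs[[ref_id]]) else unname(seqs[[1]])
    } else if (!is.null(ref_structure)) {
      structure_sequence(ref_structure)
    } else NULL

  if (mode == "from-msa") {
    msa <- read_msa(config$msa)
    if (is.null(ref_sequence)) {
      if (!(ref_id %in% names(msa)))
        stop("reference id '", ref_id, "' not present in the MSA")
      ref_sequence <- degap(msa[[ref_id]])
    }
    sites <- extract_sites_from_msa(msa, ref_id, pocket,
                                    ref_sequence = ref_sequence,
                                    ref_structure = ref_structure)
    reports <- data.frame(member_id = sites$member_id,
                          reference_id = ref_id,
                          percent_identity = vapply(sites$member_id,
                            function(id)
                              percent_identity(msa_pair(msa, ref_id, id)),
                            numeric(1)),
                          stringsAsFactors = FALSE)
  } else {
    ## detect-pocket / known-pocket / from-models: pairwise alignments
    if (is.null(ref_sequence))
      stop("a reference sequence is required (PDB or FASTA)")
    alns <- load_alignments(config, ref_id, ref_sequence, notes)
    notes <- alns$notes
    reports <- do.call(rbind, lapply(alns$alignments, function(a)
      data.frame(member_id = a$target_id, reference_id = a$ref_id,
                 percent_identity = percent_identity(a),
                 stringsAsFactors = FALSE)))
    gate <- apply_identity_gate(reports, config$id_threshold)
    keep_ids <- gate$kept$member_id
    site_rows <- lapply(alns$alignments[match(keep_ids,
                          vapply(alns$alignments, `[[`, character(1),
                                 "target_id"))],
                        map_pocket_through_alignment,
                        pocket = pocket, ref_sequence = ref_sequence,
                        ref_structure = ref_structure)
    sites <- do.call(rbind, site_rows)
    return(list(sites = sites, discarded = gate$discarded, notes = notes))
  }
  gate <- apply_identity_gate(reports, config$id_threshold)
  sites <- sites[sites$member_id %in% gate$kept$member_id, , drop = FALSE]
  list(sites = sites, discarded = gate$discarded, notes = notes)
}

## Alignments from a directory of aligned-FASTA pairs; targets without a
## file fall back to the global aligner against the reference sequence.
load_alignments <- function(config, ref_id, ref_sequence, notes) {
  alignments <- list()
  if (!is.null(config$alignments)) {
    files <- sort(list.files(config$alignments, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    alignments <- lapply(files, read_pairwise_alignment_fasta)
  }
  have <- vapply(alignments, `[[`, character(1), "target_id")
  targets <- character(0)
  if (!is.null(config$models)) {
    pdbs <- sort(list.files(config$models, pattern = "\\.pdb$",
                            full.names = TRUE))
    structs <- lapply(pdbs, read_pdb)
    targets <- vapply(structs, `[[`, character(1), "id")
    miss <- which(!(targets %in% have))
    if (length(miss) > 0L) {
      notes <- c(notes, sprintf(
        "no alignment file for %d model(s); used the fallback global aligner",
        length(miss)))
      fallback <- lapply(structs[miss], function(st)
        global_align(ref_sequence, structure_sequence(st),
                     ref_id = ref_id, target_id = st$id))
      alignments <- c(alignments, fallback)
    }
  } else if (!is.null(config$sequences)) {
    seqs <- read_fasta(config$sequences)
    seqs <- seqs[setdiff(names(seqs), c(ref_id, have))]
    if (length(seqs) > 0L && is.null(config$alignments)) {
      notes <- c(notes, sprintf(
        "no alignment files supplied; used the fallback global aligner for %d sequence(s)",
        length(seqs)))
      alignments <- c(alignments, lapply(names(seqs), function(id)
        global_align(ref_sequence, seqs[[id]], ref_id = ref_id,
                     target_id = id)))
    }
  }
  if (length(alignments) == 0L)
    stop("no pairwise alignments available: supply an alignments ",
         "directory, a models directory, or member sequences")
  list(alignments = alignments, notes = notes)
}
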