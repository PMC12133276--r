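## Tabular outputs: groups TSV, per-cluster FASTA files, discard log,
## sites TSV. All TSVs are tab-delimited UTF-8 with LF line endings and a
## header row, so identical inputs give byte-identical files.

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the per-member groups table
#'
#' One row per clustered member: `member_id`, `site`, `cluster` (0 =
#' unclustered), `reference_id`. Rows are ordered by cluster number (noise
#' last), then by member order.
#'
#' @param result A `site_clustering`.
#' @param sites The `active_sites` the clustering was computed from.
#' @param path Output TSV path.
#' @export
write_groups_tsv <- function(result, sites, path) {
  i <- match(result$member_ids, sites$member_id)
  if (anyNA(i)) stop("clustering contains member ids absent from the sites")
  df <- data.frame(member_id = result$member_ids,
                   site = sites$site[i],
                   cluster = result$labels,
                   reference_id = sites$reference_id[i],
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster == 0L, df$cluster), , drop = FALSE]
  write_tsv(df, path)
}

#' Read a groups table back
#'
#' @param path Path to a TSV written by [write_groups_tsv()].
#' @return Data frame with columns `member_id`, `site`, `cluster`,
#'   `reference_id`.
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(member_id = "character",
                                         site = "character",
                                         cluster = "integer",
                                         reference_id = "character"))
  if (nrow(df) == 0L) stop("empty groups file: ", path)
  df
}

#' Write one FASTA of full sequences per cluster
#'
#' Files are named `cluster_<k>.fasta`; noise members go to
#' `unclustered.fasta`. Members without a sequence are skipped silently
#' (e.g. when clustering started from a sites table).
#'
#' @param result A `site_clustering`.
#' @param sequences Named character vector of full-length sequences.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_cluster_fastas <- function(result, sequences, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in sort(unique(result$labels))) {
    ids <- result$member_ids[result$labels == l]
    ids <- ids[ids %in% names(sequences)]
    if (length(ids) == 0L) next
    tag <- if (l == 0L) "unclustered" else paste0("cluster_", l)
    p <- file.path(dir, paste0(tag, ".fasta"))
    write_fasta(sequences[ids], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the discard log
#'
#' One line per discarded member: `id<TAB>reason`.
#'
#' @param discards Data frame with columns `id`, `reason`.
#' @param path Output path.
#' @export
write_discard_log <- function(discards, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(discards) > 0L)
    writeLines(paste(discards$id, discards$reason, sep = "\t"), con,
               sep = "\n")
  invisible(path)
}

#' Write / read an active-sites table
#'
#' Columns: `member_id`, `site`, `reference_id`, `mode`. This table is the
#' re-entry point for re-clustering runs.
#'
#' @param sites An `active_sites` data frame.
#' @param path TSV path.
#' @export
write_sites_tsv <- function(sites, path) {
  write_tsv(as.data.frame(sites), path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty sites file: ", path)
  active_sites(df$member_id, df$site, df$reference_id, df$mode)
}
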