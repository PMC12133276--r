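## Per-cluster summaries: position frequency matrices, information
## content, consensus sites, cluster reports, and the 2D-vs-3D site
## comparison.

#' Position frequency matrix of a set of site strings
#'
#' @param cluster_sites Character vector of equal-length site strings
#'   (or an `active_sites` data frame).
#' @return Numeric matrix, rows = positions `1..L`, columns = the site
#'   alphabet (20 residues, `-`, `X`); every row sums to 1.
#' @export
frequency_matrix <- function(cluster_sites) {
  if (is.data.frame(cluster_sites)) cluster_sites <- cluster_sites$site
  if (length(cluster_sites) == 0L)
    stop("cannot build a frequency matrix from an empty cluster")
  if (length(unique(nchar(cluster_sites))) != 1L)
    stop("site strings have unequal lengths")
  L <- nchar(cluster_sites[1])
  cm <- matrix(unlist(strsplit(cluster_sites, "", fixed = TRUE)),
               nrow = length(cluster_sites), byrow = TRUE)
  pfm <- t(apply(cm, 2, function(col)
    table(factor(col, levels = SITE_ALPHABET)) / length(col)))
  rownames(pfm) <- seq_len(L)
  pfm
}

#' Per-position information content in bits
#'
#' `IC(k) = log2(alphabet_size) - H(k)` with `H` the Shannon entropy (bits)
#' of the residue composition at position k. Gaps are excluded from the
#' entropy and scale the IC by the non-gap fraction; no small-sample
#' correction is applied.
#'
#' @param pfm A position frequency matrix from [frequency_matrix()].
#' @param alphabet_size Residue alphabet size for the maximum (default 20).
#' @return Numeric vector of per-position bits.
#' @export
information_content <- function(pfm, alphabet_size = 20) {
  res_cols <- setdiff(colnames(pfm), AA_GAP)
  apply(pfm, 1, function(p) {
    nongap <- sum(p[res_cols])
    if (nongap <= 0) return(0)
    q <- p[res_cols] / nongap
    q <- q[q > 0]
    h <- -sum(q * log2(q))
    nongap * (log2(alphabet_size) - h)
  })
}

#' Consensus site of a position frequency matrix
#'
#' The most frequent symbol at each position; ties are broken in favour of
#' residues over gap, then lexicographically.
#'
#' @param pfm A position frequency matrix.
#' @return Single consensus string.
#' @export
consensus_site <- function(pfm) {
  ord <- c(sort(setdiff(colnames(pfm), AA_GAP)), AA_GAP)
  p <- pfm[, ord, drop = FALSE]
  paste(ord[apply(p, 1, which.max)], collapse = "")
}

#' Compare 2D- and 3D-derived active sites
#'
#' For every member present in both site sets, the fraction of positions
#' with identical characters is reported, together with the family-level
#' mean and a per-position mismatch tally. Members present in only one
#' set are listed separately. The comparison is symmetric in its two
#' arguments.
#'
#' @param sites_2d,sites_3d `active_sites` data frames indexed by
#'   `member_id`.
#' @return A `site_agreement` list: `per_member` (data frame `member_id`,
#'   `agreement`), `mean_agreement`, `position_mismatches` (integer
#'   vector), `only_first`, `only_second`.
#' @export
compare_2d_3d <- function(sites_2d, sites_3d) {
  shared <- intersect(sites_2d$member_id, sites_3d$member_id)
  if (length(shared) == 0L)
    stop("the two site sets share no member ids")
  s1 <- sites_2d$site[match(shared, sites_2d$member_id)]
  s2 <- sites_3d$site[match(shared, sites_3d$member_id)]
  if (nchar(s1[1]) != nchar(s2[1]))
    stop("2D and 3D sites have different lengths")
  L <- nchar(s1[1])
  m1 <- matrix(unlist(strsplit(s1, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  m2 <- matrix(unlist(strsplit(s2, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  eq <- m1 == m2
  structure(list(per_member = data.frame(member_id = shared,
                                         agreement = rowMeans(eq),
                                         stringsAsFactors = FALSE),
                 mean_agreement = mean(rowMeans(eq)),
                 position_mismatches = stats::setNames(colSums(!eq),
                                                       seq_len(L)),
                 only_first = setdiff(sites_2d$member_id, shared),
                 only_second = setdiff(sites_3d$member_id, shared)),
            class = "site_agreement")
}

#' @export
print.site_agreement <- function(x, ...) {
  cat(sprintf("2D/3D site agreement over %d shared member(s): mean %.3f\n",
              nrow(x$per_member), x$mean_agreement))
  mm <- x$position_mismatches[x$position_mismatches > 0]
  if (length(mm) > 0L)
    cat("  mismatching positions:",
        paste(sprintf("%s(%d)", names(mm), mm), collapse = " "), "\n")
  invisible(x)
}

#' Write per-cluster summary and frequency matrices
#'
#' Writes `summary.tsv` (cluster, size, consensus site, mean within-cluster
#' distance), one `pfm_cluster_<k>.tsv` per cluster, and — when noise is
#' present — an `unclustered` summary row plus `pfm_unclustered.tsv`.
#' Optionally renders one PNG logo per cluster.
#'
#' @param result A `site_clustering`.
#' @param sites The `active_sites` the clustering was computed from.
#' @param score The `score_matrix` (for mean within-cluster distances).
#' @param dir Output directory (created if needed).
#' @param render_logos Render `logo_cluster_<k>.png` files (default FALSE).
#' @return Invisibly, the summary data frame.
#' @export
write_cluster_report <- function(result, sites, score, dir,
                                 render_logos = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  site_of <- stats::setNames(sites$site, sites$member_id)
  labs <- sort(unique(result$labels))
  rows <- list()
  for (l in labs) {
    ids <- result$member_ids[result$labels == l]
    pfm <- frequency_matrix(unname(site_of[ids]))
    tag <- if (l == 0L) "unclustered" else as.character(l)
    pfm_df <- data.frame(position = rownames(pfm),
                         as.data.frame(pfm, check.names = FALSE),
                         check.names = FALSE)
    write_tsv(pfm_df, file.path(dir, paste0("pfm_cluster_", tag, ".tsv")))
    if (render_logos && l != 0L)
      render_logo(pfm, file.path(dir, paste0("logo_cluster_", tag, ".png")),
                  title = paste("Cluster", tag))
    mean_d <- if (length(ids) > 1L)
      mean(score[ids, ids][upper.tri(score[ids, ids])]) else 0
    rows[[length(rows) + 1L]] <-
      data.frame(cluster = tag, size = length(ids),
                 consensus = consensus_site(pfm),
                 mean_within_distance = round(mean_d, 6),
                 stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  ## clusters first (by number), unclustered last
  ord <- order(summary$cluster == "unclustered",
               suppressWarnings(as.integer(summary$cluster)))
  summary <- summary[ord, , drop = FALSE]
  write_tsv(summary, file.path(dir, "summary.tsv"))
  invisible(summary)
}

#' Render a simple sequence logo PNG
#'
#' Letters are stacked per position, scaled by their share of the
#' position's information content. The numeric frequency matrices are the
#' package's contract; this rendering is a convenience view.
#'
#' @param pfm A position frequency matrix.
#' @param path PNG output path.
#' @param title Plot title.
#' @export
render_logo <- function(pfm, path, title = "") {
  ic <- information_content(pfm)
  L <- nrow(pfm)
  grDevices::png(path, width = 120 + 60 * L, height = 480, res = 96)
  on.exit(grDevices::dev.off())
  ymax <- max(log2(20), max(ic))
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, ymax),
                 xlab = "site position", ylab = "bits", main = title,
                 xaxt = "n", bty = "l")
  graphics::axis(1, at = seq_len(L))
  pal <- c(aliphatic = "#404040", aromatic = "#7a378b", polar = "#1f9e57",
           basic = "#2a5caa", acidic = "#d62728", special = "#e8882e")
  res_cols <- setdiff(colnames(pfm), AA_GAP)
  for (k in seq_len(L)) {
    p <- pfm[k, res_cols]
    p <- p[p > 0]
    if (length(p) == 0L || ic[k] <= 0) next
    p <- sort(p / sum(p))          # tallest letter on top
    y <- 0
    for (s in names(p)) {
      h <- p[[s]] * ic[k]
      col <- if (s %in% AA_STANDARD) pal[[aa_class_of(s)]] else "grey50"
      graphics::text(k, y + h / 2, s, cex = 0.6 + 3.4 * min(h / ymax, 1),
                     col = col, font = 2)
      y <- y + h
    }
  }
  invisible(path)
}
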