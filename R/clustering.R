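## Density-based clustering (DBSCAN) on the precomputed site score matrix,
## with automatic parameter selection, deterministic size-ordered cluster
## numbering and re-clustering of individual groups.

#' DBSCAN on a precomputed distance matrix
#'
#' Standard DBSCAN semantics: a point is a core point iff at least
#' `min_samples` points (itself included) lie within distance `eps`;
#' clusters are the connected components of core points under
#' eps-reachability together with their border points; everything else is
#' noise (label 0). Border points are claimed by the first cluster that
#' reaches them under a deterministic index-order expansion, so results
#' are reproducible for a fixed input order.
#'
#' @param score A `score_matrix` (or any symmetric distance matrix with
#'   ids as dimnames).
#' @param eps Neighbourhood radius in score-matrix units, in `(0, 1]`.
#' @param min_samples Density threshold (>= 1, <= n).
#' @param auto Flag recorded in the result stating whether the parameters
#'   were chosen automatically.
#' @return A `site_clustering`: list with `member_ids`, `labels` (named
#'   integer vector; clusters `1..K` numbered by decreasing size, noise
#'   `0`), `params` and `cluster_sizes`.
#' @export
dbscan_sites <- function(score, eps, min_samples, auto = FALSE) {
  n <- nrow(score)
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) ||
      eps <= 0 || eps > 1)
    stop("eps must lie in (0, 1]")
  min_samples <- as.integer(min_samples)
  if (is.na(min_samples) || min_samples < 1L || min_samples > n)
    stop("min_samples must be an integer in [1, n]")
  ids <- rownames(score)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  nb <- lapply(seq_len(n), function(i) which(score[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(NA_integer_, n)       # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!core[i]) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]; qpos <- qpos + 1L
      if (is.na(labels[j]) || labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]])
      }
    }
  }
  params <- list(eps = eps, min_samples = min_samples, auto = auto)
  order_clusters(labels, ids, params)
}

#' Renumber raw cluster labels by decreasing size
#'
#' Clusters are renumbered `1..K` by decreasing size; ties are broken by
#' the smallest contained member index. Noise stays 0.
#'
#' @param raw_labels Integer vector; 0 marks noise.
#' @param member_ids Ids parallel to `raw_labels`.
#' @param params A parameter list to store in the result.
#' @return A `site_clustering`.
#' @export
order_clusters <- function(raw_labels, member_ids = NULL, params = NULL) {
  n <- length(raw_labels)
  if (is.null(member_ids)) member_ids <- as.character(seq_len(n))
  labs <- unique(raw_labels[raw_labels != 0L])
  if (length(labs) > 0L) {
    size <- vapply(labs, function(l) sum(raw_labels == l), integer(1))
    firsts <- vapply(labs, function(l) min(which(raw_labels == l)),
                     integer(1))
    ord <- labs[order(-size, firsts)]
    new <- match(raw_labels, ord)
    new[raw_labels == 0L] <- 0L
  } else {
    new <- rep(0L, n)
  }
  names(new) <- member_ids
  sizes <- table(new[new != 0L])
  structure(list(member_ids = member_ids,
                 labels = new,
                 params = params,
                 cluster_sizes = stats::setNames(as.integer(sizes),
                                                 names(sizes))),
            class = "site_clustering")
}

#' @export
print.site_clustering <- function(x, ...) {
  k <- length(x$cluster_sizes)
  cat("Site clustering: ", length(x$labels), " members, ", k, " cluster(s), ",
      sum(x$labels == 0L), " unclustered\n", sep = "")
  if (!is.null(x$params))
    cat(sprintf("  eps = %.4g, min_samples = %d%s\n", x$params$eps,
                x$params$min_samples,
                if (isTRUE(x$params$auto)) " (auto)" else ""))
  if (k > 0L)
    cat("  sizes:", paste(sprintf("%s:%d", names(x$cluster_sizes),
                                  x$cluster_sizes), collapse = " "), "\n")
  invisible(x)
}

#' Automatic DBSCAN parameter selection
#'
#' `min_samples` is set to `max(5, round(ln n))`. `eps` is read off the
#' k-distance curve (each point's distance to its `min_samples`-th nearest
#' neighbour, self included, sorted ascending): the candidate radii are
#' the distinct curve values between the 80th and 95th percentile ranks —
#' the curve's upper bend, where the dense regime hands over to density
#' outliers — and the candidate whose clustering maximises a silhouette
#' score on the precomputed distances (noise points contributing zero) is
#' kept. A flat curve has a single candidate, the constant itself. `eps`
#' is clamped to `(0, 1]`.
#'
#' Site score matrices concentrate on a few discrete values, so curvature
#' reading of the k-distance curve is unstable, and a single fixed
#' quantile can land exactly on the distance level of rare between-group
#' bridge pairs (one such pair between two core points merges two
#' clusters). Scoring the few candidate levels by silhouette detects such
#' collapses directly and is deterministic. Both parameters remain
#' user-overridable.
#'
#' @param score A `score_matrix` with at least 5 members.
#' @return List `(eps, min_samples, auto = TRUE)`.
#' @export
auto_params <- function(score) {
  n <- nrow(score)
  if (n < 5L)
    stop("automatic parameter selection needs at least 5 members; ",
         "supply eps and min_samples manually")
  min_samples <- max(5L, as.integer(round(log(n))))
  kdist <- vapply(seq_len(n), function(i) sort(score[i, ])[min_samples],
                  numeric(1))
  curve <- sort(kdist)
  cands <- unique(curve[seq(ceiling(0.80 * n), ceiling(0.95 * n))])
  cands <- pmin(pmax(cands, .Machine$double.eps), 1)
  if (length(cands) > 12L)   # thin near-continuous curves
    cands <- unique(cands[round(seq(1, length(cands), length.out = 12L))])
  eps <- cands[length(cands)]
  if (length(cands) > 1L) {
    best_score <- -Inf
    for (e in cands) {
      cl <- dbscan_sites(score, e, min_samples)
      k <- length(cl$cluster_sizes)
      if (k == 0L) next
      in_cl <- cl$labels != 0L
      val <- if (k == 1L) {
        mean(in_cl) - 1           # single cluster: prefer less noise
      } else {
        sil <- cluster::silhouette(as.integer(cl$labels[in_cl]),
                                   dmatrix = unclass(score)[in_cl, in_cl,
                                                            drop = FALSE])
        sum(sil[, "sil_width"]) / n
      }
      if (val > best_score + 1e-12) { best_score <- val; eps <- e }
    }
  }
  list(eps = eps, min_samples = min_samples, auto = TRUE)
}

#' Re-cluster one cluster of a previous result
#'
#' Restricts the score matrix to the chosen cluster's members and runs
#' DBSCAN again, either with explicit parameters or with [auto_params()]
#' recomputed on the submatrix. Subsets too small to support the requested
#' density are returned as a single cluster with a warning.
#'
#' @param result A `site_clustering`.
#' @param score The `score_matrix` the result was computed from.
#' @param cluster_label Label of the cluster to subdivide.
#' @param eps,min_samples Optional explicit parameters; when both are
#'   `NULL`, parameters are chosen automatically on the subset.
#' @return A fresh `site_clustering` over the subset's members.
#' @export
recluster <- function(result, score, cluster_label, eps = NULL,
                      min_samples = NULL) {
  cluster_label <- as.integer(cluster_label)
  if (!(cluster_label %in% result$labels) || cluster_label == 0L)
    stop("cluster label ", cluster_label, " not present in the clustering")
  ids <- result$member_ids[result$labels == cluster_label]
  sub <- score[ids, ids, drop = FALSE]
  class(sub) <- class(score)
  auto <- is.null(eps) && is.null(min_samples)
  if (auto) {
    if (nrow(sub) < 5L) {
      warning("cluster ", cluster_label, " has fewer than 5 members; ",
              "returning it as a single cluster")
      return(order_clusters(rep(1L, nrow(sub)), ids,
                            list(eps = NA_real_, min_samples = NA_integer_,
                                 auto = TRUE)))
    }
    p <- auto_params(sub)
    eps <- p$eps; min_samples <- p$min_samples
  } else {
    if (is.null(eps) || is.null(min_samples))
      stop("supply both eps and min_samples, or neither")
    if (min_samples > nrow(sub)) {
      warning("cluster ", cluster_label, " is smaller than min_samples; ",
              "returning it as a single cluster")
      return(order_clusters(rep(1L, nrow(sub)), ids,
                            list(eps = eps, min_samples = min_samples,
                                 auto = FALSE)))
    }
  }
  dbscan_sites(sub, eps, min_samples, auto = auto)
}
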