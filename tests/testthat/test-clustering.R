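## DBSCAN on precomputed distances, automatic parameters, ordering,
## re-clustering.

two_blob_matrix <- function(n1, n2, within = 0.05, between = 0.9) {
  n <- n1 + n2
  D <- matrix(between, n, n)
  D[1:n1, 1:n1] <- within
  D[(n1 + 1):n, (n1 + 1):n] <- within
  diag(D) <- 0
  dimnames(D) <- list(paste0("m", 1:n), paste0("m", 1:n))
  D
}

test_that("degenerate geometries cluster as expected", {
  D <- matrix(0, 6, 6); dimnames(D) <- list(letters[1:6], letters[1:6])
  cl <- dbscan_sites(D, eps = 0.1, min_samples = 3)
  expect_true(all(cl$labels == 1L))

  ## one point far from a tight blob becomes noise
  D <- matrix(0, 5, 5); D[5, ] <- D[, 5] <- 1; diag(D) <- 0
  dimnames(D) <- list(letters[1:5], letters[1:5])
  cl <- dbscan_sites(D, eps = 0.2, min_samples = 3)
  expect_equal(unname(cl$labels), c(1L, 1L, 1L, 1L, 0L))
})

test_that("invalid parameters are rejected", {
  D <- two_blob_matrix(3, 3)
  expect_error(dbscan_sites(D, eps = 0, min_samples = 2), "eps")
  expect_error(dbscan_sites(D, eps = 1.5, min_samples = 2), "eps")
  expect_error(dbscan_sites(D, eps = 0.5, min_samples = 0), "min_samples")
  expect_error(dbscan_sites(D, eps = 0.5, min_samples = 7), "min_samples")
})

test_that("dbscan matches the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    D <- random_distance_matrix(n)
    eps <- stats::runif(1, 0.05, 1)
    ms <- sample(1:min(n, 10), 1)
    got <- dbscan_sites(D, eps, ms)
    oracle <- brute_dbscan(D, eps, ms)
    expect_identical(canon_labels(unname(got$labels)), canon_labels(oracle),
                     info = sprintf("n=%d eps=%.3f ms=%d", n, eps, ms))
  }
})

test_that("clusters are numbered by decreasing size with index tie-break", {
  raw <- c(7L, 7L, 0L, 3L, 3L, 3L)
  cl <- order_clusters(raw)
  expect_equal(unname(cl$labels), c(2L, 2L, 0L, 1L, 1L, 1L))
  ## equal sizes: the cluster holding the earliest member gets number 1
  raw <- c(5L, 9L, 5L, 9L)
  cl <- order_clusters(raw)
  expect_equal(unname(cl$labels), c(1L, 2L, 1L, 2L))
  ## all noise
  cl <- order_clusters(c(0L, 0L))
  expect_equal(length(cl$cluster_sizes), 0)
})

test_that("labels are invariant to input permutation on unambiguous instances", {
  D <- two_blob_matrix(6, 4)
  cl <- dbscan_sites(D, eps = 0.1, min_samples = 3)
  set.seed(8)
  perm <- sample(10)
  Dp <- D[perm, perm]
  clp <- dbscan_sites(Dp, eps = 0.1, min_samples = 3)
  expect_identical(clp$labels[rownames(D)], cl$labels)
})

test_that("automatic parameters separate well-spaced blobs", {
  D <- two_blob_matrix(50, 50)
  p <- auto_params(D)
  expect_equal(p$min_samples, 5)
  expect_true(p$eps >= 0.05 && p$eps < 0.9)
  cl <- dbscan_sites(D, p$eps, p$min_samples, auto = TRUE)
  expect_equal(length(cl$cluster_sizes), 2)
  expect_equal(sum(cl$labels == 0L), 0)

  ## constant curve: eps defaults to the constant, one cluster results
  D0 <- matrix(0.3, 8, 8); diag(D0) <- 0
  dimnames(D0) <- list(paste0("m", 1:8), paste0("m", 1:8))
  p0 <- auto_params(D0)
  expect_equal(p0$eps, 0.3)
  cl0 <- dbscan_sites(D0, p0$eps, p0$min_samples)
  expect_true(all(cl0$labels == 1L))

  expect_error(auto_params(two_blob_matrix(2, 2)), "at least 5")
})

test_that("planted groups are recovered with automatic parameters", {
  ## between-group site distance >= 3x within-group distance by design
  for (s in 1:5) {
    fam <- generate_family(family_spec(4, 25, 10, 50, p_noise = 0.03,
                                       p_gap = 0.01, seed = 100 + s))
    sites <- extract_sites_from_msa(fam$msa, fam$reference_id, fam$pocket)
    sc <- build_score_matrix(sites)
    p <- auto_params(sc)
    cl <- dbscan_sites(sc, p$eps, p$min_samples, auto = TRUE)
    expect_gte(ari_vs_truth(cl, fam$true_labels), 0.95)
  }
})

test_that("recluster restricts to the chosen cluster and can subdivide it", {
  ## nested structure: cluster 1 holds two sub-blobs at distance 0.3,
  ## cluster 2 is a distant tight blob
  n <- 18
  D <- matrix(0.9, n, n)
  D[1:6, 1:6] <- 0.05; D[7:12, 7:12] <- 0.05
  D[1:6, 7:12] <- D[7:12, 1:6] <- 0.3
  D[13:18, 13:18] <- 0.05
  diag(D) <- 0
  dimnames(D) <- list(paste0("m", 1:n), paste0("m", 1:n))
  cl <- dbscan_sites(D, eps = 0.35, min_samples = 3)
  expect_equal(length(cl$cluster_sizes), 2)
  expect_equal(unname(cl$cluster_sizes["1"]), 12L)

  sub <- recluster(cl, D, 1, eps = 0.1, min_samples = 3)
  expect_equal(length(sub$cluster_sizes), 2)
  expect_setequal(sub$member_ids, paste0("m", 1:12))
  ## oracle agreement on the submatrix
  oracle <- brute_dbscan(D[1:12, 1:12], 0.1, 3)
  expect_identical(canon_labels(unname(sub$labels)), canon_labels(oracle))

  ## reclustering a pure cluster reproduces it
  pure <- recluster(cl, D, 2, eps = 0.1, min_samples = 3)
  expect_true(all(pure$labels == 1L))

  expect_error(recluster(cl, D, 99), "99")
  expect_warning(recluster(cl, D, 2, eps = 0.1, min_samples = 10),
                 "smaller than min_samples")
})

test_that("recluster on the full set reproduces dbscan", {
  set.seed(77)
  D <- random_distance_matrix(30)
  cl_all <- dbscan_sites(D, 0.4, 4)
  one <- order_clusters(rep(1L, 30), rownames(D))
  again <- recluster(one, D, 1, eps = 0.4, min_samples = 4)
  expect_identical(again$labels, cl_all$labels)
})
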