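## Frequency matrices, information content, consensus, 2D/3D comparison,
## cluster reports.

test_that("frequency matrix tallies columns", {
  pfm <- frequency_matrix("AK")
  expect_equal(pfm[1, "A"], 1)
  expect_equal(pfm[2, "K"], 1)
  pfm <- frequency_matrix(c("A", "C"))
  expect_equal(pfm[1, "A"], 0.5)
  expect_equal(pfm[1, "C"], 0.5)
  ## hand tally over 4 mixed sites
  pfm <- frequency_matrix(c("AK", "AK", "C-", "AX"))
  expect_equal(pfm[1, "A"], 3 / 4)
  expect_equal(pfm[1, "C"], 1 / 4)
  expect_equal(pfm[2, "K"], 2 / 4)
  expect_equal(pfm[2, "-"], 1 / 4)
  expect_equal(pfm[2, "X"], 1 / 4)
  expect_error(frequency_matrix(character(0)), "empty")
})

test_that("frequency matrix rows sum to one for random clusters", {
  set.seed(13)
  for (i in 1:50) {
    pfm <- frequency_matrix(random_sites(sample(1:20, 1), sample(1:12, 1)))
    expect_equal(unname(rowSums(pfm)), rep(1, nrow(pfm)), tolerance = 1e-9)
    expect_true(all(pfm >= 0))
  }
})

test_that("information content has its closed forms and bounds", {
  ## uniform over the 20 residues -> 0 bits
  u <- matrix(0, 1, 22, dimnames = list(1, c(AA_STANDARD, "-", "X")))
  u[1, AA_STANDARD] <- 1 / 20
  expect_equal(unname(information_content(u)), 0, tolerance = 1e-9)
  ## single residue -> log2(20) bits
  s <- matrix(0, 1, 22, dimnames = list(1, c(AA_STANDARD, "-", "X")))
  s[1, "W"] <- 1
  expect_equal(unname(information_content(s)), log2(20), tolerance = 1e-9)
  ## 50/50 two residues -> log2(20) - 1
  h <- matrix(0, 1, 22, dimnames = list(1, c(AA_STANDARD, "-", "X")))
  h[1, c("A", "G")] <- 0.5
  expect_equal(unname(information_content(h)), log2(20) - 1,
               tolerance = 1e-9)
  ## half gaps scale the IC by the non-gap fraction
  g <- matrix(0, 1, 22, dimnames = list(1, c(AA_STANDARD, "-", "X")))
  g[1, "W"] <- 0.5; g[1, "-"] <- 0.5
  expect_equal(unname(information_content(g)), log2(20) / 2,
               tolerance = 1e-9)
  ## bounds and mixing monotonicity on random columns
  set.seed(19)
  for (i in 1:50) {
    pfm <- frequency_matrix(random_sites(10, 5))
    ic <- information_content(pfm)
    expect_true(all(ic >= -1e-12 & ic <= log2(20) + 1e-12))
  }
  ## mixing a pure column toward uniform decreases IC
  expect_gt(information_content(s)[1], information_content(h)[1])
  expect_gt(information_content(h)[1], information_content(u)[1])
})

test_that("consensus picks the argmax with deterministic tie-break", {
  expect_identical(consensus_site(frequency_matrix(c("AK", "AK", "CK"))),
                   "AK")
  ## tie A/C at position 1 -> lexicographically smallest
  expect_identical(consensus_site(frequency_matrix(c("AK", "CK"))), "AK")
  ## residue preferred over gap on ties
  expect_identical(consensus_site(frequency_matrix(c("W", "-"))), "W")
})

test_that("compare_2d_3d reports per-member agreement symmetrically", {
  a <- active_sites(c("m1", "m2"), c("ACDEFGHIKL", "ACDEFGHIKL"),
                    "r", rep("2d", 2))
  b <- active_sites(c("m2", "m1", "m3"),
                    c("ACDEFGHIKV", "ACDEFGHIKL", "AAAAAAAAAA"),
                    "r", rep("3d", 3))
  r <- compare_2d_3d(a, b)
  expect_equal(r$per_member$agreement[r$per_member$member_id == "m1"], 1.0)
  expect_equal(r$per_member$agreement[r$per_member$member_id == "m2"], 0.9)
  expect_equal(r$mean_agreement, 0.95)
  expect_equal(unname(r$position_mismatches[10]), 1)
  expect_identical(r$only_second, "m3")
  ## symmetric
  r2 <- compare_2d_3d(b, a)
  expect_equal(r2$mean_agreement, r$mean_agreement)
  expect_equal(sort(r2$per_member$agreement), sort(r$per_member$agreement))
  ## identical inputs -> all ones
  expect_equal(compare_2d_3d(a, a)$mean_agreement, 1.0)
  ## disjoint ids -> error
  c2 <- active_sites("z9", "ACDEFGHIKL", "r", "3d")
  expect_error(compare_2d_3d(a, c2), "share no member")
})

test_that("cluster report writes summary, PFMs and an unclustered section", {
  sites <- active_sites(paste0("m", 1:5),
                        c("AK", "AK", "AK", "CD", "W-"),
                        "ref", rep("2d", 5))
  sc <- build_score_matrix(sites)
  cl <- dbscan_sites(sc, eps = 0.1, min_samples = 2)
  d <- withr::local_tempdir()
  sm <- write_cluster_report(cl, sites, sc, d)
  expect_true(file.exists(file.path(d, "summary.tsv")))
  expect_true(file.exists(file.path(d, "pfm_cluster_1.tsv")))
  expect_true(file.exists(file.path(d, "pfm_cluster_unclustered.tsv")))
  ## cluster of identical sites: consensus equals the site, distance 0
  expect_identical(sm$consensus[sm$cluster == "1"], "AK")
  expect_equal(sm$mean_within_distance[sm$cluster == "1"], 0)
  ## noise-only clustering -> only the unclustered section
  noise <- order_clusters(rep(0L, 5), sites$member_id)
  d2 <- withr::local_tempdir()
  sm2 <- write_cluster_report(noise, sites, sc, d2)
  expect_identical(sm2$cluster, "unclustered")
})

test_that("logo rendering writes a PNG when asked", {
  pfm <- frequency_matrix(c("AKW", "AKW", "CK-"))
  f <- withr::local_tempfile(fileext = ".png")
  render_logo(pfm, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
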