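## Identity computation, reference selection, pocket mapping, gap discard,
## and the fallback global aligner.

aln <- function(r, t, rid = "ref", tid = "tgt")
  pairwise_alignment(rid, tid, r, t)

test_that("percent identity counts matches over both-non-gap columns", {
  expect_equal(percent_identity(aln("ACDE", "ACDE")), 100)
  expect_equal(percent_identity(aln("AC-E", "ACDE")), 100)  # 3/3 non-gap
  expect_equal(percent_identity(aln("AAAA", "CCCC")), 0)
  expect_equal(percent_identity(aln("ACDE", "ACEE")), 75)
  ## symmetric in its two rows
  set.seed(3)
  for (i in 1:10) {
    a <- global_align(paste(sample(AA_STANDARD, 10, TRUE), collapse = ""),
                      paste(sample(AA_STANDARD, 8, TRUE), collapse = ""))
    flipped <- pairwise_alignment("t", "r", a$target_row, a$ref_row)
    expect_equal(percent_identity(a), percent_identity(flipped))
  }
})

test_that("reference selection takes the best identity, first on ties", {
  alns <- list(aln("AAAA", "AACC", rid = "refA"),   # 50%
               aln("AAAA", "AAAC", rid = "refB"),   # 75%
               aln("AAAA", "AAAC", rid = "refC"))   # 75% tie
  sel <- select_reference(alns)
  expect_identical(sel$reference_id, "refB")
  sel2 <- select_reference(alns[c(1, 3, 2)])
  expect_identical(sel2$reference_id, "refC")  # first of the tied pair
  expect_identical(select_reference(alns[1])$reference_id, "refA")
  expect_error(select_reference(list()), "no alignments")
})

test_that("identity gate is inclusive at the threshold", {
  reports <- data.frame(member_id = c("low", "edge", "high"),
                        reference_id = "r",
                        percent_identity = c(29.9, 30.0, 62.0))
  g <- apply_identity_gate(reports, threshold = 30)
  expect_identical(g$kept$member_id, c("edge", "high"))
  expect_identical(g$discarded$id, "low")
  expect_match(g$discarded$reason, "identity<30")
  g0 <- apply_identity_gate(reports, threshold = 0)
  expect_equal(nrow(g0$discarded), 0)
})

test_that("pocket mapping follows reference columns across gaps", {
  pocket <- function(pos, seq)
    pocket_definition("ref", rep("A", length(pos)), pos, ref_sequence = seq)
  ## identity alignment, pocket at reference indices 1,3,5
  s <- map_pocket_through_alignment(aln("ACDEF", "ACDEF"),
                                    pocket(c(1, 3, 5), "ACDEF"), "ACDEF")
  expect_identical(s$site, "ADF")
  expect_identical(s$mode, "3d")
  ## deletion in the target becomes '-'
  s <- map_pocket_through_alignment(aln("ACDEF", "AC-EF"),
                                    pocket(c(1, 3, 5), "ACDEF"), "ACDEF")
  expect_identical(s$site, "A-F")
  ## hand-traced bookkeeping across a reference gap:
  ## ref "AC-DE" -> residues at columns 1,2,4,5; pocket indices 3,4 ->
  ## columns 4,5 -> target "ACXDE" reads "DE"
  s <- map_pocket_through_alignment(aln("AC-DE", "ACXDE"),
                                    pocket(c(3, 4), "ACDE"), "ACDE")
  expect_identical(s$site, "DE")
  ## pocket beyond the reference errors
  expect_error(map_pocket_through_alignment(aln("ACDE", "ACDE"),
                                            pocket(5, "ACDEF"), "ACDE"),
               "beyond")
})

test_that("MSA extraction matches the reference-column protocol", {
  pocket <- pocket_definition("ref", c("A", "A"), c(2, 4),
                              ref_sequence = "ACDE")
  msa <- as_msa(c(ref = "ACDE", m1 = "ACDE", m2 = "AKDW", m3 = "----"))
  s <- extract_sites_from_msa(msa, "ref", pocket)
  expect_identical(s$member_id, c("m1", "m2", "m3"))
  expect_identical(s$site, c("CE", "KW", "--"))
  expect_true(all(s$mode == "2d"))
  ## an insertion column before the pocket leaves sites unchanged
  msa_ins <- as_msa(c(ref = "-ACDE", m1 = "WACDE", m2 = "-AKDW",
                      m3 = "W----"))
  s2 <- extract_sites_from_msa(msa_ins, "ref", pocket)
  expect_identical(s2$site, s$site)
  expect_error(extract_sites_from_msa(msa, "nope", pocket), "nope")
})

test_that("gap discard removes exactly the sites above the threshold", {
  sites <- active_sites(c("a", "b", "c"),
                        c("----AW--", "ACDE-FGH", "ACDEFGHI"),
                        "ref", rep("2d", 3))
  g <- apply_gap_discard(sites, max_gap_fraction = 0.5)
  expect_identical(g$kept$member_id, c("b", "c"))   # 6/8 gaps discarded
  expect_identical(g$discarded$id, "a")
  expect_match(g$discarded$reason, "gap_fraction>0.5")
  expect_equal(nrow(apply_gap_discard(sites, 1.0)$discarded), 0)
})

test_that("global aligner: identical sequences score the diagonal sum", {
  b62 <- siteclust:::blosum62()
  set.seed(5)
  for (i in 1:5) {
    s <- paste(sample(AA_STANDARD, 8, TRUE), collapse = "")
    a <- global_align(s, s)
    expect_identical(a$ref_row, s)       # gap-free
    expect_identical(a$target_row, s)
    cc <- strsplit(s, "")[[1]]
    expect_equal(a$score, sum(b62[cbind(cc, cc)]))
  }
  m <- global_align("A", "G")
  expect_identical(m$ref_row, "A")
  expect_identical(m$target_row, "G")
})

test_that("global aligner matches exhaustive enumeration on short pairs", {
  b62 <- siteclust:::blosum62()
  set.seed(99)
  for (i in 1:40) {
    a <- paste(sample(AA_STANDARD, sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(AA_STANDARD, sample(1:6, 1), TRUE), collapse = "")
    got <- global_align(a, b)
    expect_equal(got$score, enum_align_score(a, b, b62),
                 info = paste(a, b))
    ## emitted rows must reproduce the claimed score
    expect_identical(degap(got$ref_row), a)
    expect_identical(degap(got$target_row), b)
  }
})

test_that("3D-mode and 2D-mode sites agree on MSA-consistent alignments", {
  fam <- generate_family(family_spec(3, 8, 6, 30, seed = 123))
  sites2d <- extract_sites_from_msa(fam$msa, fam$reference_id, fam$pocket)
  refseq <- fam$sequences[[fam$reference_id]]
  sites3d <- do.call(rbind, lapply(fam$alignments,
    map_pocket_through_alignment, pocket = fam$pocket,
    ref_sequence = refseq))
  i <- match(sites2d$member_id, sites3d$member_id)
  expect_identical(sites2d$site, sites3d$site[i])
})
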