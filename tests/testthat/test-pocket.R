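## Pocket definition: P2RANK parsing, selection, ligand proximity, user lists.

make_ref_structure <- function() {
  generate_toy_structure(paste(rep("A", 50), collapse = ""),
                         site_residue_indices = c(5, 10, 15))
}

test_that("P2RANK candidates are sorted by score with ties in file order", {
  st <- make_ref_structure()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name, score , residue_ids",
               "pocket1,3.2,A_1 A_2",
               "pocket2,9.1,A_3 A_4",
               "pocket3,3.2,A_5"), f)
  cand <- parse_p2rank_predictions(f, st)
  expect_equal(cand[[1]]$score, 9.1)
  expect_identical(cand[[1]]$name, "pocket2")
  ## tie at 3.2: file order wins
  expect_identical(cand[[2]]$name, "pocket1")
  expect_identical(cand[[3]]$name, "pocket3")

  expect_equal(select_pocket(cand)$score, 9.1)
  expect_identical(select_pocket(cand, rank = 2)$name, "pocket1")
  expect_error(select_pocket(cand, rank = 4), "out of range")
})

test_that("P2RANK residues must resolve against the structure", {
  st <- make_ref_structure()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,score,residue_ids", "p1,5.0,A_999"), f)
  expect_error(parse_p2rank_predictions(f, st), "A_999")
  writeLines("name,score,residue_ids", f)
  expect_error(parse_p2rank_predictions(f, st), "empty")
})

test_that("pocket positions are ordered and deduplicated regardless of input order", {
  st <- make_ref_structure()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,score,residue_ids", "p1,5.0,A_12 A_45 A_7"), f)
  cand <- parse_p2rank_predictions(f, st)
  p <- pocket_definition(st$id, cand[[1]]$residues$chain,
                         cand[[1]]$residues$resno,
                         cand[[1]]$residues$insert, structure = st,
                         source = "p2rank")
  expect_equal(p$resno, c(7, 12, 45))

  p1 <- pocket_from_user_list("ref", c("A_10", "A_3", "A_10"), structure = st)
  expect_equal(p1$resno, c(3, 10))
  p2 <- pocket_from_user_list("ref", c("A_3", "A_10"), structure = st)
  expect_equal(p1$resno, p2$resno)
  expect_error(pocket_from_user_list("ref", "B_5", structure = st), "B_5")
})

test_that("ligand proximity keeps exactly the residues within the cutoff", {
  ## 5 single-atom residues at controlled distances from a ligand at origin
  dists <- c(2.0, 4.0, 4.4, 4.6, 10.0)
  atoms <- data.frame(type = "ATOM", chain = "A", resno = 1:5, insert = "",
                      resid = "ALA", elety = "CA", element = "C",
                      x = dists, y = 0, z = 0, stringsAsFactors = FALSE)
  het <- data.frame(type = "HETATM", chain = "A", resno = 9, insert = "",
                    resid = "LIG", elety = "C1", element = "C",
                    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  residues <- data.frame(chain = "A", resno = 1:5, insert = "",
                         resname = "ALA", aa = "A", stringsAsFactors = FALSE)
  st <- structure(list(id = "toy", chains = "A", residues = residues,
                       atoms = atoms, het_atoms = het),
                  class = "parsed_structure")
  p <- detect_pocket_by_ligand(st, cutoff = 4.5)
  expect_equal(p$resno, c(1, 2, 3))
  expect_identical(attr(p, "source"), "ligand_proximity")
  ## and it matches the brute-force oracle
  expect_identical(sort(paste(p$chain, p$resno, p$insert, sep = "_")),
                   brute_pocket_residues(st, 4.5, het))
})

test_that("ligand proximity needs a HET group", {
  st <- make_ref_structure()
  st$het_atoms <- st$het_atoms[0, ]
  expect_error(detect_pocket_by_ligand(st), "HET")
})

test_that("ligand proximity agrees with the brute-force oracle on random structures", {
  set.seed(42)
  for (i in 1:30) {
    st <- random_toy_structure(sample(5:50, 1))
    cutoff <- stats::runif(1, 3, 12)
    oracle <- brute_pocket_residues(st, cutoff, st$het_atoms)
    got <- tryCatch({
      p <- detect_pocket_by_ligand(st, cutoff = cutoff)
      sort(paste(p$chain, p$resno, p$insert, sep = "_"))
    }, error = function(e) character(0))
    expect_identical(got, oracle)
  }
})

test_that("pocket TSV round-trips", {
  st <- make_ref_structure()
  p <- pocket_from_user_list("toy", c("A_5", "A_10", "A_15"), structure = st)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pocket_tsv(p, f)
  p2 <- read_pocket_tsv(f)
  expect_equal(p2$resno, p$resno)
  expect_identical(p2$aa, p$aa)
  expect_identical(attr(p2, "reference_id"), "toy")
})
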