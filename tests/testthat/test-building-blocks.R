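test_that("canonicalisation is idempotent and tolerant of dirty input", {
  smi <- c("OCC", "C(O)C", "CC(=O)[O-].[Na+]")
  canon <- canon_smiles(strip_salts(smi), neutralize = TRUE)
  expect_equal(canon[1], canon[2])
  expect_equal(canon[3], canon_smiles("CC(=O)O"))
  expect_equal(canon_smiles(canon), canon)
})

test_that("loading counts rejects instead of silently dropping them", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("Nc1cnccn1 a1", "Nc1cncc(Cl)n1 a2", "not_a_smiles((( bad",
               "Nc1cncc(F)n1 a3"), f)
  blocks <- load_blocks(f)
  expect_s3_class(blocks, "fl_blocks")
  expect_equal(nrow(blocks), 3L)
  expect_equal(attr(blocks, "n_rejected"), 1L)
  expect_equal(attr(blocks, "rejects")$id, "bad")
})

test_that("loading an empty or missing file errors", {
  f <- tempfile(fileext = ".smi")
  writeLines(character(), f)
  expect_error(load_blocks(f), "no records")
  expect_error(load_blocks(tempfile()), "not found")
})

test_that("role classification follows the substructure patterns", {
  expect_equal(classify_block("Nc1cncc(Cl)n1"), "amino_heteroarene")
  expect_equal(classify_block("O=S(=O)(Cl)c1ccc(C)cc1"),
               "sulfonyl_chloride")
  expect_equal(classify_block("c1ccccc1"), "unknown")
  # aliphatic amines and anilines are outside the coupling chemistry
  expect_equal(classify_block("NCCCC"), "unknown")
  expect_equal(classify_block("Nc1ccccc1"), "unknown")
  # a block carrying both reactive groups is flagged, not guessed
  both <- "Nc1cncc(n1)c1ccc(cc1)S(Cl)(=O)=O"
  expect_equal(classify_block(both), "ambiguous")
})

test_that("classification is pure and order-independent", {
  fx <- load_fixture_blocks(4, 5)
  all_blocks <- rbind(fx$amines, fx$sulfonyls)
  shuffled <- all_blocks[rev(seq_len(nrow(all_blocks))), ]
  r1 <- classify_structures(all_blocks$structure)
  r2 <- rev(classify_structures(shuffled$structure))
  expect_equal(r1, r2)
  # labels match the generator's ground truth exactly
  truth <- fx$fx$truth
  expect_equal(
    classify_structures(canon_smiles(truth$structure)), truth$role)
})

test_that("scaffold query hits products and misses fragments", {
  expect_true(match_scaffold("O=S(=O)(Nc1cnccn1)c1ccccc1"))
  expect_false(match_scaffold("c1cnccn1"))
  expect_false(match_scaffold("Nc1cnccn1"))
  expect_error(match_scaffold("not_a_smiles((("), "invalid")
})

test_that("retro-decomposition inverts the coupling", {
  prod <- couple("Nc1cnccn1", "O=S(=O)(Cl)c1ccccc1")
  expect_equal(nrow(prod), 1L)
  rd <- retro_decompose(prod$structure)
  expect_equal(rd$amine, canon_smiles("Nc1cnccn1"))
  expect_equal(rd$sulfonyl_chloride,
               canon_smiles("O=S(=O)(Cl)c1ccccc1"))
  # molecules without the sulfonamide scaffold yield an empty list
  expect_equal(nrow(retro_decompose("CC")), 0L)
  expect_equal(nrow(retro_decompose("c1ccccc1")), 0L)
})

test_that("reactive-site counting sees every site", {
  m <- mol_from_smiles("Nc1cncc(N)n1")   # two equivalent amine sites
  expect_length(find_amine_sites(m), 2L)
  s <- mol_from_smiles("O=S(=O)(Cl)c1ccc(cc1)S(Cl)(=O)=O")
  expect_length(find_sulfonyl_sites(s), 2L)
})
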