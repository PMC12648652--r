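test_that("coupling applies the N-sulfonylation transform", {
  p <- couple("Nc1cnccn1", "O=S(=O)(Cl)c1ccccc1")
  expect_equal(p$structure, canon_smiles("O=S(=O)(Nc1cnccn1)c1ccccc1"))
  expect_error(couple("c1ccccc1", "O=S(=O)(Cl)c1ccccc1"),
               "amino_heteroarene")
  expect_error(couple("Nc1cnccn1", "c1ccccc1"), "sulfonyl_chloride")
})

test_that("symmetric diamines collapse to one product after dedup", {
  # two equivalent amino sites on pyrazine-2,6-diamine
  p <- couple("Nc1cncc(N)n1", "O=S(=O)(Cl)c1ccccc1")
  expect_equal(nrow(p), 1L)
})

test_that("enumeration equals the template-level brute-force oracle", {
  fx <- load_fixture_blocks(3, 4)
  lib <- enumerate_library(fx$amines, fx$sulfonyls)
  expect_equal(nrow(lib), 12L)
  oracle <- oracle_library(.substituent_palette_test(3),
                           .substituent_palette_test(4))
  expect_equal(lib$structure, oracle)
  # every product keeps its provenance pair
  expect_true(all(nzchar(lib$amine_id)))
  expect_true(all(grepl("^AM", lib$amine_id)))
  expect_true(all(grepl("^SC", lib$sulfonyl_id)))
})

test_that("enumeration is permutation-invariant and dedup-idempotent", {
  fx <- load_fixture_blocks(3, 3)
  lib1 <- enumerate_library(fx$amines, fx$sulfonyls)
  shuf_a <- fx$amines[c(3, 1, 2), ]
  shuf_s <- fx$sulfonyls[c(2, 3, 1), ]
  lib2 <- enumerate_library(shuf_a, shuf_s)
  expect_equal(lib1$structure, lib2$structure)
  expect_equal(lib1$product_id, lib2$product_id)
  # doubling the block lists adds nothing new
  lib3 <- enumerate_library(rbind(fx$amines, fx$amines),
                            rbind(fx$sulfonyls, fx$sulfonyls))
  expect_equal(lib3$structure, lib1$structure)
})

test_that("empty role classes fail with the class named", {
  fx <- load_fixture_blocks(2, 2)
  none <- fx$amines[0, ]
  expect_error(enumerate_library(none, fx$sulfonyls),
               "amino_heteroarene")
  expect_error(enumerate_library(fx$amines, fx$sulfonyls[0, ]),
               "sulfonyl_chloride")
})

test_that("library files round-trip losslessly with a count manifest", {
  fx <- load_fixture_blocks(2, 3)
  lib <- enumerate_library(fx$amines, fx$sulfonyls)
  path <- tempfile(fileext = ".smi")
  man <- write_library(lib, path)
  expect_equal(man$count, nrow(lib))
  back <- read_library(path)
  expect_equal(back$structure, lib$structure)
  expect_equal(back$product_id, lib$product_id)
  expect_equal(back$amine_id, lib$amine_id)
  # truncation is detected via the manifest
  lines <- readLines(path)
  writeLines(head(lines, -2L), path)
  expect_error(read_library(path), "truncated")
  # malformed records are reported by line
  writeLines(c("#h", "only_two\tfields"), path)
  expect_error(read_library(path), "malformed")
})

test_that("product ids are stable hashes of the canonical structure", {
  id1 <- product_id("O=S(=O)(Nc1cnccn1)c1ccccc1")
  id2 <- product_id("O=S(=O)(Nc1cnccn1)c1ccccc1")
  expect_identical(id1, id2)
  expect_match(id1, "^P[0-9a-f]{16}$")
  expect_false(id1 == product_id("O=S(=O)(Nc1cnccn1)c1ccc(F)cc1"))
})
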