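test_that("molecules without ionisable or tautomeric groups are inert", {
  expect_equal(enumerate_protomers("C1CCCCC1"),
               canon_smiles("C1CCCCC1"))
  expect_equal(enumerate_tautomers("c1ccccc1"), canon_smiles("c1ccccc1"))
  # keto-enol shifts are outside the rule set: acetone stays itself
  expect_equal(enumerate_tautomers("CC(C)=O"), canon_smiles("CC(C)=O"))
})

test_that("a basic centre with pKa inside the window yields two states", {
  # 1-methylimidazole: pyridine-type ring nitrogen, pKa ~7
  states <- enumerate_protomers("Cn1ccnc1")
  expect_length(states, 2L)
  expect_true(canon_smiles("Cn1ccnc1") %in% states)
  expect_true(any(grepl("+", states, fixed = TRUE)))
})

test_that("sites decisively outside the window give a single state", {
  # morpholine (pKa 8.36, window 6.0-7.2 +/- 1.0): protonated only
  m <- enumerate_protomers("C1COCCN1")
  expect_length(m, 1L)
  expect_true(grepl("+", m, fixed = TRUE))
  # carboxylic acid (pKa 4.2): anion only
  a <- enumerate_protomers("CC(=O)O")
  expect_length(a, 1L)
  expect_true(grepl("-", a, fixed = TRUE))
  # pyrazine ring nitrogens (pKa ~0.6): neutral only
  expect_equal(enumerate_protomers("c1cnccn1"), canon_smiles("c1cnccn1"))
})

test_that("lactam/lactim tautomers are both enumerated", {
  t1 <- enumerate_tautomers("Oc1ccccn1")
  expect_true(canon_smiles("Oc1ccccn1") %in% t1)
  expect_true(canon_smiles("O=c1cccc[nH]1") %in% t1)
  # closure: starting from the lactam reaches the same set
  t2 <- enumerate_tautomers("O=c1cccc[nH]1")
  expect_setequal(t1, t2)
})

test_that("widening the pH window never reduces the species count", {
  probes <- c("C1COCCN1", "Cn1ccnc1", "CC(=O)O", "Nc1cnccn1",
              "O=S(=O)(Nc1cnccn1)c1ccc(O)cc1")
  narrow <- state_config(ph_min = 6.0, ph_max = 7.2)
  wide <- state_config(ph_min = 3.0, ph_max = 11.0)
  for (p in probes) {
    expect_gte(length(enumerate_protomers(p, wide)),
               length(enumerate_protomers(p, narrow)))
  }
})

test_that("library expansion tracks provenance and stage counts", {
  fx <- load_fixture_blocks(3, 4)
  lib <- enumerate_library(fx$amines, fx$sulfonyls)
  sp <- expand_library(lib)
  expect_s3_class(sp, "fl_species")
  # every species maps to exactly one parent; counts are conserved
  expect_true(all(sp$parent_product_id %in% lib$product_id))
  per_parent <- table(sp$parent_product_id)
  expect_equal(sum(per_parent), nrow(sp))
  expect_true(all(per_parent >= 1L))
  man <- attr(sp, "manifest")
  expect_equal(man$products_in, nrow(lib))
  expect_equal(man$species_out, nrow(sp))
  expect_match(man$tautomer_ruleset, "1,3-shift")
  # no duplicated (parent, structure) pairs
  expect_false(any(duplicated(sp[, c("parent_product_id", "structure")])))
})

test_that("expansion at a fixed config is idempotent", {
  fx <- load_fixture_blocks(2, 2)
  lib <- enumerate_library(fx$amines, fx$sulfonyls)
  sp1 <- expand_library(lib)
  sp2 <- expand_library(lib)
  expect_identical(sp1$structure, sp2$structure)
  expect_identical(sp1$species_id, sp2$species_id)
  # re-expanding the emitted neutral species adds nothing new per parent
  neutral <- sp1[sp1$kind == "parent", ]
  relib <- data.frame(product_id = neutral$parent_product_id,
                      structure = neutral$structure)
  sp3 <- expand_library(relib)
  expect_setequal(sp3$structure, sp1$structure)
})

test_that("an empty library expands to an empty species table", {
  fx <- load_fixture_blocks(2, 2)
  lib <- enumerate_library(fx$amines, fx$sulfonyls)
  expect_equal(nrow(expand_library(lib[0, ])), 0L)
})

test_that("species files round-trip", {
  fx <- load_fixture_blocks(2, 2)
  sp <- expand_library(enumerate_library(fx$amines, fx$sulfonyls))
  path <- tempfile(fileext = ".smi")
  write_species(sp, path)
  back <- read_species(path)
  expect_equal(back$structure, sp$structure)
  expect_equal(back$species_id, sp$species_id)
  expect_equal(back$kind, sp$kind)
})
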