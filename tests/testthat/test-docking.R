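test_that("conformer embedding is deterministic and geometrically sane", {
  m1 <- embed_conformer("CC(C)c1ccccc1CCN", seed = 11)
  m2 <- embed_conformer("CC(C)c1ccccc1CCN", seed = 11)
  expect_identical(m1$atoms, m2$atoms)
  # methane: five atoms, tetrahedral within tolerance
  met <- embed_conformer("C", seed = 1)
  expect_equal(nrow(met$atoms), 5L)
  xyz <- as.matrix(met$atoms[, c("x", "y", "z")])
  dch <- sqrt(rowSums((xyz[2:5, , drop = FALSE] -
                         xyz[rep(1L, 4L), ])^2))
  expect_true(all(abs(dch - dch[1]) < 0.05))
  ang <- function(i, j, k) {
    v1 <- xyz[i, ] - xyz[j, ]; v2 <- xyz[k, ] - xyz[j, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  hh <- c(ang(2, 1, 3), ang(2, 1, 4), ang(2, 1, 5), ang(3, 1, 4))
  expect_true(all(abs(hh - 109.47) < 5))
})

test_that("ligand PDBQT preparation conserves heavy atoms", {
  pk <- gen_pocket()
  lig <- embed_conformer("CCOc1ccccc1", seed = 3)
  prep <- prepare_inputs(pk$receptor, lig, dir = tempdir())
  expect_true(file.exists(prep$ligand_pdbqt))
  expect_true(file.exists(prep$receptor_pdbqt))
  # a rigid ring-only ligand declares zero active torsions
  ring <- embed_conformer("c1ccccc1", seed = 3)
  prep2 <- prepare_inputs(pk$receptor, ring, dir = tempdir())
  tors <- grep("active torsions", readLines(prep2$ligand_pdbqt),
               value = TRUE)
  expect_match(tors, "0 active torsions")
})

test_that("the mock engine score equals its brute-force definition", {
  pk <- gen_pocket()
  cfg <- dock_config(c(0, 0, 0), c(20, 20, 20), engine = "mock",
                     seed = 42)
  lig <- embed_conformer("Clc1ccccc1", seed = cfg$seed)
  res <- dock(lig, pk$receptor, cfg)
  # brute force: place heavy atoms at the box centre, count contacts
  lx <- as.matrix(lig$atoms[lig$atoms$elem != "H", c("x", "y", "z")])
  lx <- sweep(lx, 2L, colMeans(lx))
  rx <- as.matrix(pk$receptor$atoms[pk$receptor$atoms$elem != "H",
                                    c("x", "y", "z")])
  contacts <- 0L; clashes <- 0L
  for (i in seq_len(nrow(lx))) {
    d <- sqrt(colSums((t(rx) - lx[i, ])^2))
    if (any(d <= 4.0)) contacts <- contacts + 1L
    clashes <- clashes + sum(d < 2.0)
  }
  expect_equal(res$poses[[1]]$score, -0.1 * contacts + 1.0 * clashes)
})

test_that("a ligand placed outside the pocket scores zero", {
  pk <- gen_pocket()
  cfg <- dock_config(c(500, 500, 500), c(20, 20, 20), engine = "mock")
  lig <- embed_conformer("CCO", seed = 1)
  res <- dock(lig, pk$receptor, cfg)
  expect_equal(res$poses[[1]]$score, 0)
})

test_that("best-pose selection takes the minimum with rank tie-break", {
  mk <- function(scores, ranks = seq_along(scores)) {
    structure(list(poses = Map(function(s, r) {
      list(rank = r, score = s, xyz = NULL)
    }, scores, ranks)), class = "fl_dock_result")
  }
  expect_equal(select_best_pose(mk(c(-7.2, -6.8, -6.1)))$score, -7.2)
  tie <- select_best_pose(mk(c(-5.0, -5.0)))
  expect_equal(tie$rank, 1L)
  # permutation invariance
  perm <- select_best_pose(mk(c(-6.1, -7.2, -6.8), c(3L, 1L, 2L)))
  expect_equal(perm$score, -7.2)
  expect_equal(perm$rank, 1L)
  expect_error(select_best_pose(structure(list(poses = list()),
                                          class = "fl_dock_result")),
               "no poses")
})

test_that("screening is deterministic across workers and input order", {
  pk <- gen_pocket()
  fx <- load_fixture_blocks(2, 2)
  sp <- expand_library(enumerate_library(fx$amines, fx$sulfonyls))
  cfg <- dock_config(c(0, 0, 0), c(20, 20, 20), engine = "mock",
                     seed = 42)
  t1 <- screen(sp, pk$receptor, cfg, workers = 1L)
  t4 <- screen(sp, pk$receptor, cfg, workers = 4L)
  expect_identical(t1, t4)
  shuffled <- sp[rev(seq_len(nrow(sp))), ]
  t_rev <- screen(shuffled, pk$receptor, cfg, workers = 1L)
  expect_identical(t1, t_rev)
  expect_equal(nrow(t1), nrow(sp))
})

test_that("unembeddable species become skip rows, not aborts", {
  pk <- gen_pocket()
  sp <- data.frame(
    species_id = c("S1", "S2"),
    structure = c("CCO", "this_is_not_a_molecule((("),
    stringsAsFactors = FALSE
  )
  cfg <- dock_config(c(0, 0, 0), c(20, 20, 20), engine = "mock")
  tab <- screen(sp, pk$receptor, cfg)
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$status == "ok"), 1L)
  expect_match(tab$status[tab$species_id == "S2"], "skip")
})

test_that("the external engine fails actionably when absent", {
  pk <- gen_pocket()
  cfg <- dock_config(c(0, 0, 0), c(20, 20, 20), engine = "external_vina",
                     vina_bin = "definitely-not-a-vina-binary")
  lig <- embed_conformer("CCO", seed = 1)
  expect_error(dock(lig, pk$receptor, cfg), "not found on the PATH")
})

test_that("config digests change iff a field changes", {
  c1 <- dock_config(c(0, 0, 0), c(20, 20, 20), seed = 42)
  c2 <- dock_config(c(0, 0, 0), c(20, 20, 20), seed = 42)
  c3 <- dock_config(c(0, 0, 0), c(20, 20, 20), seed = 43)
  expect_identical(c1$digest, c2$digest)
  expect_false(c1$digest == c3$digest)
})
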