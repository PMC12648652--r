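mk_scores <- function(ids, scores, structures = NULL) {
  structure(data.frame(
    species_id = ids,
    structure = if (is.null(structures)) paste0("C", seq_along(ids))
                else structures,
    best_score = scores,
    status = "ok",
    stringsAsFactors = FALSE
  ), class = c("fl_scores", "data.frame"))
}

test_that("ranking sorts ascending with a canonical tie-break", {
  tab <- mk_scores(c("A", "B", "C"), c(-9.5, -7.0, -8.2))
  expect_equal(rank_hits(tab)$species_id, c("A", "C", "B"))
  # ties break on structure, invariant under permutation
  tie <- mk_scores(c("A", "B"), c(-7, -7), c("CCO", "CCC"))
  r1 <- rank_hits(tie)
  r2 <- rank_hits(tie[2:1, ])
  expect_equal(r1$species_id, r2$species_id)
  expect_equal(r1$species_id, c("B", "A"))   # CCC sorts before CCO
  # skip rows sink below scored rows
  sk <- mk_scores(c("A", "B"), c(NA, -1))
  expect_equal(rank_hits(sk)$species_id, c("B", "A"))
})

test_that("ranking a mock screen matches a brute-force sort", {
  pk <- gen_pocket()
  fx <- load_fixture_blocks(3, 4)
  sp <- expand_library(enumerate_library(fx$amines, fx$sulfonyls))
  sp <- sp[sp$kind == "parent", ]
  cfg <- dock_config(c(0, 0, 0), c(20, 20, 20), engine = "mock")
  scored <- screen(sp, pk$receptor, cfg)
  ranked <- rank_hits(scored)
  ord <- order(scored$best_score, scored$structure)
  expect_equal(ranked$species_id, scored$species_id[ord])
})

test_that("contact filtering keeps predicate passers in rank order", {
  pk <- gen_pocket()
  prof_hit <- profile_pose(pk$receptor, pk$ligand)
  lig_far <- pk$ligand
  lig_far$atoms$x <- lig_far$atoms$x + 100
  prof_miss <- profile_pose(pk$receptor, lig_far)
  ranked <- rank_hits(mk_scores(c("H", "M"), c(-5, -4)))
  profs <- list(H = prof_hit, M = prof_miss)
  pred <- pred_contacts_to(c(302, 303, 304), min_n = 2L)
  kept <- filter_contacts(ranked, profs, list(pred))
  expect_equal(kept$species_id, "H")
  rep <- attr(kept, "predicate_report")
  expect_equal(rep$predicate_1, c(TRUE, FALSE))
  # empty predicate list is the identity filter
  expect_equal(filter_contacts(ranked, profs, list())$species_id,
               ranked$species_id)
  # missing profile is a contract error naming the species
  expect_error(filter_contacts(ranked, profs["H"], list(pred)), "M")
})

test_that("motif counts equal per-molecule brute-force matching", {
  structures <- c("Cc1ccc(cc1)S(=O)(=O)Nc1cnccn1",
                  "Fc1ccc(cc1)S(=O)(=O)Nc1cnccn1",
                  "c1ccc(cc1)S(=O)(=O)Nc1cnccn1")
  tab <- motif_table(data.frame(structure = structures),
                     c(methyl_on_aryl = "[CH3][c;R]",
                       fluoro_on_aryl = "F[c;R]",
                       nothing = "[Au]"))
  expect_equal(tab$count, c(1L, 1L, 0L))
  expect_equal(tab$fraction, c(1 / 3, 1 / 3, 0))
  brute <- vapply(structures, function(s) {
    smarts_match(s, "F[c;R]")
  }, TRUE)
  expect_equal(tab$count[tab$motif == "fluoro_on_aryl"], sum(brute))
})

test_that("novelty is a bounded max-Tanimoto against the references", {
  self <- novelty("Cc1ccccc1O", "Cc1ccccc1O")
  expect_equal(self$max_similarity, 1.0)
  # structurally unrelated molecules score low but in [0, 1]
  far <- novelty("CCCCCCCC", "c1ccc2c(c1)ccc1ccccc12")
  expect_gte(far$max_similarity, 0)
  expect_lt(far$max_similarity, 0.2)
  multi <- novelty("Cc1ccccc1O",
                   c("CCCCCCCC", "Cc1ccccc1O", "c1ccccc1"))
  expect_equal(multi$max_similarity, 1.0)
  expect_equal(multi$nearest_reference, 2L)
  expect_gte(multi$mean_similarity, far$max_similarity / 3)
  expect_error(novelty("CCO", character()), "empty")
})

test_that("fingerprints have the requested folded length", {
  fp <- circular_fp(c("CCO", "c1ccccc1"), radius = 2L, nbits = 1024L)
  expect_equal(dim(fp), c(2L, 1024L))
  expect_gt(sum(fp[1, ]), 0L)
  expect_equal(tanimoto(fp[1, ], fp[1, ]), 1)
  expect_equal(tanimoto(rep(FALSE, 8), rep(FALSE, 8)), 0)
})

test_that("reports round-trip and digest their configuration", {
  hits <- mk_scores(c("A", "B"), c(-2, -1))
  dir <- tempfile()
  cfg <- triage_config(top_n = 5L)
  man <- write_report(rank_hits(hits), dir, config = cfg)
  expect_equal(man$n_hits, 2L)
  back <- read_report(dir)
  expect_equal(back$species_id, c("A", "B"))
  # empty hit list still yields a valid report
  man0 <- write_report(rank_hits(hits)[0, ], tempfile(), config = cfg)
  expect_equal(man0$n_hits, 0L)
  # manifest digest changes iff the config changes
  expect_identical(config_digest(triage_config(top_n = 5L)),
                   config_digest(triage_config(top_n = 5L)))
  expect_false(identical(config_digest(triage_config(top_n = 5L)),
                         config_digest(triage_config(top_n = 6L))))
})
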