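test_that("the toy pocket's golden contact list is reproduced exactly", {
  pk <- gen_pocket()
  prof <- profile_pose(pk$receptor, pk$ligand)
  expect_equal(contact_key(prof$contacts), contact_key(pk$golden))
  # recorded geometry matches the construction (PDB has 3 decimals)
  for (k in seq_len(nrow(pk$golden))) {
    got <- prof$contacts[prof$contacts$kind == pk$golden$kind[k] &
                           prof$contacts$resnum == pk$golden$resnum[k], ]
    expect_equal(got$dist, pk$golden$dist[k], tolerance = 1e-3)
  }
  # every contact residue is inside the shell list
  keys <- paste(prof$contacts$chain, prof$contacts$resnum)
  expect_true(all(keys %in% paste(prof$shell_residues$chain,
                                  prof$shell_residues$resnum)))
})

test_that("a far ligand produces no contacts and an empty shell", {
  pk <- gen_pocket()
  lig <- pk$ligand
  lig$atoms$x <- lig$atoms$x + 100
  prof <- profile_pose(pk$receptor, lig)
  expect_equal(nrow(prof$contacts), 0L)
  expect_equal(nrow(prof$shell_residues), 0L)
})

test_that("contacts are invariant under rigid motions", {
  pk <- gen_pocket()
  ref <- profile_pose(pk$receptor, pk$ligand)
  set.seed(202)
  for (i in 1:20) {
    mo <- random_rigid_motion()
    prof <- profile_pose(apply_motion_receptor(pk$receptor, mo),
                         apply_motion_mol(pk$ligand, mo))
    expect_equal(contact_key(prof$contacts), contact_key(ref$contacts))
    expect_true(all(abs(sort(prof$contacts$dist) -
                          sort(ref$contacts$dist)) < 1e-6))
  }
})

test_that("distances exactly at a threshold are detected (closed)", {
  at <- boundary_fixture(4.0)   # exactly at the default max
  prof <- detect_hydrophobic(at$receptor, at$ligand)
  expect_equal(nrow(prof), 1L)
  expect_identical(prof$dist, 4.0)
  over <- boundary_fixture(4.001)
  expect_equal(nrow(detect_hydrophobic(over$receptor, over$ligand)), 0L)
})

test_that("hydrogen bonds obey both distance and angle rules", {
  ok <- gen_pocket(hbond_dist = 2.9, hbond_angle = 155)
  prof <- detect_hbonds(ok$receptor, ok$ligand)
  expect_true(302 %in% prof$resnum)
  # same donor-acceptor pair at 5.0 A: no bond
  far <- gen_pocket(hbond_dist = 5.0)
  expect_false(302 %in% detect_hbonds(far$receptor, far$ligand)$resnum)
  # bent geometry below the angle minimum: no bond
  bent <- gen_pocket(hbond_dist = 2.9, hbond_angle = 80)
  expect_false(302 %in% detect_hbonds(bent$receptor, bent$ligand)$resnum)
})

test_that("halogen bonds require the donor-angle geometry", {
  ok <- gen_pocket(halogen_dist = 3.3)
  prof <- detect_halogen(ok$receptor, ok$ligand)
  expect_equal(prof$resnum, 51L)
  expect_equal(prof$dist, 3.3, tolerance = 1e-3)
  far <- gen_pocket(halogen_dist = 4.6)
  expect_equal(nrow(detect_halogen(far$receptor, far$ligand)), 0L)
})

test_that("pi-stacking requires centroid distance and ring alignment", {
  ok <- gen_pocket(stack_dist = 3.8)
  prof <- detect_pistack(ok$receptor, ok$ligand)
  expect_equal(prof$resnum, 304L)
  expect_lt(prof$angle, 1)
  far <- gen_pocket(stack_dist = 6.0)
  expect_equal(nrow(detect_pistack(far$receptor, far$ligand)), 0L)
})

test_that("detectors are disjoint by kind and union to the profile", {
  pk <- gen_pocket()
  cfgd <- profiler_config()
  parts <- list(
    detect_hbonds(pk$receptor, pk$ligand, cfgd),
    detect_hydrophobic(pk$receptor, pk$ligand, cfgd),
    detect_halogen(pk$receptor, pk$ligand, cfgd),
    detect_pistack(pk$receptor, pk$ligand, cfgd),
    detect_saltbridge(pk$receptor, pk$ligand, cfgd)
  )
  kinds <- unlist(lapply(parts, function(p) unique(p$kind)))
  expect_false(any(duplicated(kinds)))
  prof <- profile_pose(pk$receptor, pk$ligand, cfgd)
  expect_equal(contact_key(prof$contacts),
               contact_key(do.call(rbind, parts)))
})

test_that("salt bridges pair opposite formal charges", {
  pk <- gen_pocket()
  # protonate the ligand amine and park it near the Glu carboxylate
  lig <- pk$ligand
  n_idx <- which(lig$atoms$elem == "N")
  lig$atoms$chg[n_idx] <- 1L
  sb <- detect_saltbridge(pk$receptor, lig)
  expect_equal(unique(sb$resname), "GLU")
  # the neutral ligand forms none
  expect_equal(nrow(detect_saltbridge(pk$receptor, pk$ligand)), 0L)
})

test_that("prevalence counts frames satisfying the predicate", {
  pk <- gen_pocket()
  frames <- gen_frames(pk, 4, on_frames = c(1, 2, 4))
  pred <- pred_contacts_to(c(302, 303, 304), min_n = 2L)
  p <- prevalence(frames, predicate = pred)
  expect_equal(as.numeric(p), 0.75)
  expect_equal(attr(p, "per_frame"), c(TRUE, TRUE, FALSE, TRUE))
  # degenerate predicates and duplicated frames
  p0 <- prevalence(frames, predicate = pred_contacts_to(integer(), 1L))
  expect_equal(as.numeric(p0), 0)
  same <- gen_frames(pk, 3, on_frames = 1:3)
  expect_equal(as.numeric(prevalence(same, predicate = pred)), 1)
  expect_error(prevalence(list(), predicate = pred), "no frames")
})

test_that("residue maps annotate contacts without guessing", {
  pk <- gen_pocket()
  prof <- profile_pose(pk$receptor, pk$ligand)
  mapped <- apply_residue_map(prof, pk$bw_map, receptor = pk$receptor)
  glu <- mapped$contacts[mapped$contacts$resnum == 302, ]
  expect_equal(unique(glu$bw), "8.48")
  # empty map: unchanged
  un <- apply_residue_map(prof, character())
  expect_identical(un$contacts, prof$contacts)
  # key not in structure: validation error listing it
  expect_error(
    apply_residue_map(prof, c("999" = "1.50"), receptor = pk$receptor),
    "999")
})
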