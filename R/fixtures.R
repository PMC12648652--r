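# Synthetic fixtures: building-block sets with provably distinct products,
# toy receptor pockets with analytically known contact geometry, and
# seeded dose-response curves. Every generator is deterministic under its
# seed and embeds its ground truth so downstream assertions never guess.
#
# These generators are synthetic stand-ins for the kind of data the
# workflow consumes (vendor building-block files, a refined GPCR model,
# plate-reader tables); they emulate its shape and known properties, not
# any particular deposited dataset.

# Substituent palette: chemically inert ring substituents, pairwise
# distinct so that every (amine, sulfonyl) coupling is unique and
# |library| = n_amines * n_sulfonyls exactly. Series: halogens/CF3/OMe,
# then linear alkyl, alkoxy and chloroalkyl chains of growing length.
.substituent_palette <- function(n) {
  base <- c("F", "Cl", "Br", "C(F)(F)F", "OC")
  out <- base
  k <- 1L
  while (length(out) < n) {
    out <- c(out,
             strrep("C", k + 1L),                 # alkyl
             paste0("O", strrep("C", k + 1L)),    # alkoxy
             paste0(strrep("C", k), "Cl"))        # chloroalkyl
    k <- k + 1L
  }
  out[seq_len(n)]
}

#' Generate synthetic building-block files
#'
#' Writes `n_amines` substituted 2-aminopyrazines and `n_sulfonyls`
#' para-substituted benzenesulfonyl chlorides as SMILES files. All blocks
#' are canonical and role-classifiable, each has exactly one reactive
#' site, and substituents are pairwise distinct so the enumerated library
#' has exactly `n_amines * n_sulfonyls` unique products.
#'
#' @param n_amines,n_sulfonyls block counts (>= 1 each).
#' @param dir output directory.
#' @param seed seed recorded in the ground truth (generation itself is
#'   deterministic).
#' @return list with `amine_file`, `sulfonyl_file` and a `truth`
#'   data.frame (`id`, `structure`, `role`).
#' @export
gen_blocks <- function(n_amines, n_sulfonyls, dir = tempdir(), seed = 1L) {
  if (n_amines < 1L || n_sulfonyls < 1L) {
    stop("fixture spec requires at least one block of each role",
         call. = FALSE)
  }
  subs_a <- .substituent_palette(n_amines)
  subs_s <- .substituent_palette(n_sulfonyls)
  amines <- sprintf("Nc1cncc(%s)n1", subs_a)
  sulfonyls <- sprintf("O=S(=O)(Cl)c1ccc(%s)cc1", subs_s)
  a_ids <- sprintf("AM%03d", seq_len(n_amines))
  s_ids <- sprintf("SC%03d", seq_len(n_sulfonyls))
  amine_file <- file.path(dir, "amines.smi")
  sulfonyl_file <- file.path(dir, "sulfonyl_chlorides.smi")
  writeLines(paste(amines, a_ids), amine_file)
  writeLines(paste(sulfonyls, s_ids), sulfonyl_file)
  truth <- data.frame(
    id = c(a_ids, s_ids),
    structure = c(amines, sulfonyls),
    role = c(rep("amino_heteroarene", n_amines),
             rep("sulfonyl_chloride", n_sulfonyls)),
    stringsAsFactors = FALSE
  )
  list(amine_file = amine_file, sulfonyl_file = sulfonyl_file,
       truth = truth, seed = seed)
}

# unit vector at `deg` degrees in the xy-plane
.u2 <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)

# Place an acceptor A such that |donor - A| = dist and the angle
# donor-H-A equals `angle` (degrees), in the plane spanned by donor->H
# and `perp`.
.place_by_angle <- function(donor, h, dist, angle, perp = c(0, 0, 1)) {
  hd <- donor - h
  hlen <- sqrt(sum(hd^2))
  u <- hd / hlen
  th <- angle * pi / 180
  # law of cosines: dist^2 = hlen^2 + t^2 - 2 hlen t cos(th)
  t <- hlen * cos(th) + sqrt(dist^2 - hlen^2 * sin(th)^2)
  p <- perp - sum(perp * u) * u
  p <- p / sqrt(sum(p^2))
  h + t * (cos(th) * u + sin(th) * p)
}

#' Generate a toy receptor pocket with known contact geometry
#'
#' Builds a posed ligand (a chloro/methoxy/amino-substituted benzene) and
#' a minimal pocket of five residues, each placed at stated distances and
#' angles from its ligand partner: a Glu302 side-chain acceptor hydrogen
#' bond, a Lys303 donor hydrogen bond, a Val51 backbone halogen-bond
#' acceptor, a parallel-stacked Phe304 ring and a Leu236 hydrophobic
#' carbon. Returns the golden contact list implied by the construction,
#' plus the Ballesteros-Weinstein map of the conserved motif.
#'
#' @param dir directory for the receptor PDB.
#' @param hbond_dist,hbond_angle geometry of the ligand-donor hydrogen
#'   bond (A, degrees at the donor hydrogen).
#' @param halogen_dist Cl...O distance (A).
#' @param stack_dist ring-centroid separation (A).
#' @param hydrophobic_dist C...C distance (A).
#' @return list with `receptor` (`fl_receptor`), `receptor_file`,
#'   `ligand` (`fl_mol` with coordinates), `golden` (data.frame `kind`,
#'   `resnum`, `resname`, `dist`), `bw_map`.
#' @export
gen_pocket <- function(dir = tempdir(), hbond_dist = 2.9,
                       hbond_angle = 155, halogen_dist = 3.3,
                       stack_dist = 4.5, hydrophobic_dist = 3.9) {
  r <- 1.39
  ring <- t(vapply(seq(0, 300, 60), function(d) r * .u2(d), numeric(3)))
  C3 <- ring[3L, ]; C5 <- ring[5L, ]
  N <- C3 + 1.40 * .u2(120)
  H <- N + 1.01 * .u2(120)
  O <- C5 + 1.38 * .u2(240)
  CMe <- O + 1.43 * .u2(240)
  Cl <- ring[1L, ] + 1.73 * .u2(0)
  lig_atoms <- data.frame(
    elem = c(rep("C", 6L), "N", "H", "O", "C", "Cl"),
    chg = 0L,
    x = c(ring[, 1L], N[1L], H[1L], O[1L], CMe[1L], Cl[1L]),
    y = c(ring[, 2L], N[2L], H[2L], O[2L], CMe[2L], Cl[2L]),
    z = c(ring[, 3L], N[3L], H[3L], O[3L], CMe[3L], Cl[3L]),
    stringsAsFactors = FALSE
  )
  lig_bonds <- data.frame(
    a1 = c(1L, 2L, 3L, 4L, 5L, 6L, 3L, 7L, 5L, 9L, 1L),
    a2 = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 11L),
    order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)
  )
  ligand <- .fl_mol(lig_atoms, lig_bonds, title = "probe_ligand")

  # receptor atoms, placed relative to their ligand partners
  OE1 <- .place_by_angle(N, H, hbond_dist, hbond_angle)
  CD <- OE1 + 1.25 * .u2(120)
  OE2 <- CD + 1.25 * .u2(120)
  NZ <- O + 3.0 * .u2(330)
  CE <- NZ + 1.47 * .u2(330)
  OVal <- Cl + halogen_dist * .u2(0)
  xdir <- (Cl - OVal) / halogen_dist
  ydir <- .u2(90)
  CVal <- OVal + 1.23 * (cos(120 * pi / 180) * xdir +
                           sin(120 * pi / 180) * ydir)
  phe <- t(vapply(seq(30, 330, 60), function(d) {
    r * .u2(d) + c(0, 0, stack_dist)
  }, numeric(3)))
  CD1 <- ring[6L, ] + c(0, 0, -hydrophobic_dist)

  rec <- data.frame(
    elety = c("CD", "OE1", "OE2", "CE", "NZ", "C", "O",
              "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CD1"),
    resid = c(rep("GLU", 3L), rep("LYS", 2L), rep("VAL", 2L),
              rep("PHE", 6L), "LEU"),
    resno = c(rep(302L, 3L), rep(303L, 2L), rep(51L, 2L),
              rep(304L, 6L), 236L),
    stringsAsFactors = FALSE
  )
  xyz <- rbind(CD, OE1, OE2, CE, NZ, CVal, OVal, phe, CD1)
  receptor_file <- file.path(dir, "toy_pocket.pdb")
  bio3d::write.pdb(file = receptor_file,
                   xyz = as.numeric(t(xyz)),
                   resno = rec$resno, resid = rec$resid,
                   elety = rec$elety, chain = rep("A", nrow(rec)),
                   eleno = seq_len(nrow(rec)))
  receptor <- read_receptor(receptor_file)
  golden <- data.frame(
    kind = c("hbond", "hbond", "halogen_bond", "pi_stack", "hydrophobic"),
    resnum = c(302L, 303L, 51L, 304L, 236L),
    resname = c("GLU", "LYS", "VAL", "PHE", "LEU"),
    dist = c(hbond_dist, 3.0, halogen_dist, stack_dist, hydrophobic_dist),
    stringsAsFactors = FALSE
  )
  bw_map <- c("302" = "8.48", "303" = "8.49", "304" = "8.50",
              "51" = "1.53", "236" = "6.36")
  list(receptor = receptor, receptor_file = receptor_file,
       ligand = ligand, golden = golden, bw_map = bw_map)
}

#' Trajectory-like frames from a pocket fixture
#'
#' Returns `n_frames` (receptor, ligand) frames; in frames not listed in
#' `on_frames` the ligand is translated 50 A away so no contact survives.
#'
#' @param pocket a [gen_pocket()] result.
#' @param n_frames number of frames.
#' @param on_frames indices of frames where the pose (and so its
#'   contacts) is present.
#' @return list of `list(receptor =, ligand3d =)` frames.
#' @export
gen_frames <- function(pocket, n_frames, on_frames = seq_len(n_frames)) {
  lapply(seq_len(n_frames), function(i) {
    lig <- pocket$ligand
    if (!i %in% on_frames) {
      lig$atoms$x <- lig$atoms$x + 50
    }
    list(receptor = pocket$receptor, ligand3d = lig)
  })
}

#' Generate a seeded synthetic dose-response table
#'
#' Responses follow a 4PL curve at the stated parameters with Gaussian
#' noise; generating parameters are embedded for recovery tests.
#'
#' @param pic50 true pIC50 (-log10 molar midpoint).
#' @param hill true Hill slope (sign sets the direction).
#' @param top,bottom response plateaus.
#' @param noise_sd Gaussian noise standard deviation, as a fraction of
#'   the plateau span.
#' @param n_points number of (log-spaced) concentrations.
#' @param replicates replicate measurements per concentration.
#' @param seed RNG seed.
#' @param file optional CSV path (`concentration_molar,response,replicate`).
#' @return data.frame with attribute `truth`.
#' @export
gen_curves <- function(pic50 = 6, hill = 1, top = 100, bottom = 0,
                       noise_sd = 0.05, n_points = 8L, replicates = 1L,
                       seed = 1L, file = NULL) {
  stopifnot(n_points >= 4L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  logc <- seq(-pic50 - 3, -pic50 + 3, length.out = n_points)
  conc <- rep(10^logc, each = replicates)
  mu <- bottom + (top - bottom) /
    (1 + 10^((-pic50 - log10(conc)) * hill))
  resp <- mu + stats::rnorm(length(mu), 0, noise_sd * abs(top - bottom))
  out <- data.frame(
    concentration_molar = conc,
    response = resp,
    replicate = rep(seq_len(replicates), times = n_points)
  )
  attr(out, "truth") <- list(pic50 = pic50, hill = hill, top = top,
                             bottom = bottom, noise_sd = noise_sd,
                             seed = seed)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
  }
  out
}
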