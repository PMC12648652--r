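# Geometric protein-ligand interaction profiling.
#
# Rule-based detection of typed noncovalent contacts between a receptor
# structure and a posed ligand, in the style of PLIP: hydrogen bonds,
# hydrophobic contacts, halogen bonds, pi-stacking and salt bridges, each
# governed solely by distance/angle thresholds exposed in the
# configuration. All distance thresholds are closed intervals: a distance
# exactly equal to a maximum is detected.
#
# Donor/acceptor typing: on the ligand side from element plus bonding
# pattern (N/O/S with hydrogen donate; oxygens and lone-pair nitrogens
# accept); on the receptor side from a vendored per-residue atom-name
# table (backbone N donates, backbone O accepts, side chains per residue
# type). If the receptor lacks explicit hydrogens the hydrogen-bond angle
# test degrades to a donor-geometry proxy; the mode used is recorded in
# the profile.

#' Profiler configuration
#'
#' Defaults mirror the published defaults of rule-based interaction
#' profilers (donor-acceptor 4.1 A / 100 degrees for hydrogen bonds,
#' 4.0 A carbon-carbon hydrophobic, 4.0 A halogen bonds with 165/120
#' degree donor/acceptor angles and 30 degree tolerance, 5.5 A ring
#' centroids with 30 degree tolerance for stacking, 5.5 A charged-group
#' centroids for salt bridges, 5.0 A pocket shell).
#'
#' @param hbond_dist_max donor-acceptor heavy-atom maximum (A).
#' @param hbond_angle_min minimum angle at the donor hydrogen (degrees).
#' @param hydrophobic_dist_max carbon-carbon maximum (A).
#' @param halogen_dist_max X...acceptor maximum (A).
#' @param halogen_donor_angle,halogen_acceptor_angle ideal C-X...A and
#'   Y-A...X angles (degrees).
#' @param halogen_angle_tol tolerance around both ideals (degrees).
#' @param pistack_centroid_max ring-centroid distance maximum (A).
#' @param pistack_angle_tol tolerance for parallel/perpendicular ring
#'   normals (degrees).
#' @param saltbridge_dist_max charged-group centroid maximum (A).
#' @param shell_radius pocket shell radius (A).
#' @return a `fl_profiler_config`.
#' @export
profiler_config <- function(hbond_dist_max = 4.1, hbond_angle_min = 100,
                            hydrophobic_dist_max = 4.0,
                            halogen_dist_max = 4.0,
                            halogen_donor_angle = 165,
                            halogen_acceptor_angle = 120,
                            halogen_angle_tol = 30,
                            pistack_centroid_max = 5.5,
                            pistack_angle_tol = 30,
                            saltbridge_dist_max = 5.5,
                            shell_radius = 5.0) {
  vals <- c(hbond_dist_max, hbond_angle_min, hydrophobic_dist_max,
            halogen_dist_max, halogen_donor_angle, halogen_acceptor_angle,
            halogen_angle_tol, pistack_centroid_max, pistack_angle_tol,
            saltbridge_dist_max, shell_radius)
  stopifnot(all(vals > 0))
  structure(list(
    hbond_dist_max = hbond_dist_max, hbond_angle_min = hbond_angle_min,
    hydrophobic_dist_max = hydrophobic_dist_max,
    halogen_dist_max = halogen_dist_max,
    halogen_donor_angle = halogen_donor_angle,
    halogen_acceptor_angle = halogen_acceptor_angle,
    halogen_angle_tol = halogen_angle_tol,
    pistack_centroid_max = pistack_centroid_max,
    pistack_angle_tol = pistack_angle_tol,
    saltbridge_dist_max = saltbridge_dist_max,
    shell_radius = shell_radius
  ), class = "fl_profiler_config")
}

# Receptor side-chain donor/acceptor atom-name tables (backbone handled
# separately: N donates, O/OXT accept).
.REC_DONOR_ATOMS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
  GLN = "NE2", TRP = "NE1", HIS = c("ND1", "NE2"), LYS = "NZ",
  ARG = c("NE", "NH1", "NH2")
)
.REC_ACCEPTOR_ATOMS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD"
)
.REC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
.REC_POS_GROUPS <- list(LYS = "NZ", ARG = c("CZ", "NE", "NH1", "NH2"))
.REC_NEG_GROUPS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.angle_deg <- function(p1, vertex, p2) {
  v1 <- p1 - vertex; v2 <- p2 - vertex
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.dist3 <- function(p1, p2) sqrt(sum((p1 - p2)^2))

# residue-level split of the receptor atom table
.rec_residues <- function(receptor) {
  a <- receptor$atoms
  split(seq_len(nrow(a)), paste(a$chain, a$resno, a$resid, sep = "|"))
}

# ligand donor atoms: index + attached explicit H indices (may be empty)
.lig_donors <- function(lig) {
  a <- lig$atoms
  adj <- .mol_adj(lig)
  nh <- implicit_h(lig)
  idx <- which(a$elem %in% c("N", "O", "S") & a$chg >= 0L)
  idx <- idx[vapply(idx, function(i) {
    nh[i] + sum(a$elem[adj[[i]]] == "H") > 0L
  }, TRUE)]
  lapply(idx, function(i) {
    list(atom = i, h = adj[[i]][a$elem[adj[[i]]] == "H"])
  })
}

# ligand acceptor atoms: oxygens (not positively charged) and nitrogens
# with an available lone pair (no H, at most 2 heavy neighbours, neutral)
.lig_acceptors <- function(lig) {
  a <- lig$atoms
  adj <- .mol_adj(lig)
  nh <- implicit_h(lig)
  out <- integer()
  for (i in seq_len(nrow(a))) {
    if (a$chg[i] > 0L) next
    heavy <- adj[[i]][a$elem[adj[[i]]] != "H"]
    hcount <- nh[i] + sum(a$elem[adj[[i]]] == "H")
    if (a$elem[i] == "O") out <- c(out, i)
    else if (a$elem[i] == "N" && hcount == 0L && length(heavy) <= 2L) {
      out <- c(out, i)
    }
  }
  out
}

.contact_row <- function(kind, a, ridx, dist, angle, lig_atoms) {
  data.frame(kind = kind, chain = a$chain[ridx[1L]],
             resnum = a$resno[ridx[1L]], resname = a$resid[ridx[1L]],
             bw = NA_character_, dist = dist, angle = angle,
             ligand_atoms = paste(lig_atoms, collapse = ";"),
             stringsAsFactors = FALSE)
}

.empty_contacts <- function() {
  data.frame(kind = character(), chain = character(), resnum = integer(),
             resname = character(), bw = character(), dist = numeric(),
             angle = numeric(), ligand_atoms = character(),
             stringsAsFactors = FALSE)
}

#' Contact detectors
#'
#' Each detector applies exactly one geometric rule and returns the
#' contacts of its kind; [profile_pose()] is their union.
#'
#' @param receptor a `fl_receptor`.
#' @param ligand3d an `fl_mol` with 3D coordinates.
#' @param config a [profiler_config()].
#' @return data.frame of contacts (`kind`, `chain`, `resnum`, `resname`,
#'   `bw`, `dist`, `angle`, `ligand_atoms`).
#' @name detectors
NULL

#' @rdname detectors
#' @export
detect_hbonds <- function(receptor, ligand3d, config = profiler_config()) {
  a <- receptor$atoms
  lx <- .mol_xyz(ligand3d)
  la <- ligand3d$atoms
  res <- .rec_residues(receptor)
  rec_h <- which(a$elem == "H")
  has_rec_h <- length(rec_h) > 0L
  rows <- list()
  rec_pt <- function(i) c(a$x[i], a$y[i], a$z[i])
  # receptor donor/acceptor indices
  rec_don <- integer(); rec_acc <- integer()
  for (ridx in res) {
    rn <- a$resid[ridx[1L]]
    don_names <- c("N", .REC_DONOR_ATOMS[[rn]])
    acc_names <- c("O", "OXT", .REC_ACCEPTOR_ATOMS[[rn]])
    rec_don <- c(rec_don, ridx[a$name[ridx] %in% don_names])
    rec_acc <- c(rec_acc, ridx[a$name[ridx] %in% acc_names])
  }
  angle_ok_rec_donor <- function(d, acc_pt) {
    # vertex at an attached hydrogen when available, else donor proxy
    hs <- rec_h[vapply(rec_h, function(h) {
      .dist3(rec_pt(h), rec_pt(d)) <= 1.3
    }, TRUE)]
    if (has_rec_h && length(hs) > 0L) {
      ang <- max(vapply(hs, function(h) {
        .angle_deg(rec_pt(d), rec_pt(h), acc_pt)
      }, 0))
      list(ok = ang >= config$hbond_angle_min, angle = ang,
           mode = "explicit-H")
    } else {
      nb <- which(a$elem != "H" &
                    vapply(seq_len(nrow(a)), function(j) {
                      j != d && .dist3(rec_pt(j), rec_pt(d)) <= 1.8
                    }, TRUE))
      ang <- if (length(nb) == 0L) 180 else {
        min(vapply(nb, function(j) {
          .angle_deg(rec_pt(j), rec_pt(d), acc_pt)
        }, 0))
      }
      list(ok = ang >= 90, angle = ang, mode = "heavy-proxy")
    }
  }
  # ligand donors -> receptor acceptors
  for (don in .lig_donors(ligand3d)) {
    dpt <- lx[don$atom, ]
    for (acc in rec_acc) {
      apt <- rec_pt(acc)
      dd <- .dist3(dpt, apt)
      if (dd > config$hbond_dist_max) next
      if (length(don$h) > 0L) {
        ang <- max(vapply(don$h, function(h) {
          .angle_deg(dpt, lx[h, ], apt)
        }, 0))
        if (ang < config$hbond_angle_min) next
      } else {
        heavy <- .mol_adj(ligand3d)[[don$atom]]
        heavy <- heavy[la$elem[heavy] != "H"]
        ang <- if (length(heavy) == 0L) 180 else {
          min(vapply(heavy, function(j) .angle_deg(lx[j, ], dpt, apt), 0))
        }
        if (ang < 90) next
      }
      rows[[length(rows) + 1L]] <-
        .contact_row("hbond", a, acc, dd, ang, don$atom)
    }
  }
  # receptor donors -> ligand acceptors
  for (acc in .lig_acceptors(ligand3d)) {
    apt <- lx[acc, ]
    for (d in rec_don) {
      dd <- .dist3(rec_pt(d), apt)
      if (dd > config$hbond_dist_max) next
      chk <- angle_ok_rec_donor(d, apt)
      if (!chk$ok) next
      rows[[length(rows) + 1L]] <-
        .contact_row("hbond", a, d, dd, chk$angle, acc)
    }
  }
  if (length(rows) == 0L) return(.empty_contacts())
  unique(do.call(rbind, rows))
}

#' @rdname detectors
#' @export
detect_hydrophobic <- function(receptor, ligand3d,
                               config = profiler_config()) {
  a <- receptor$atoms
  lx <- .mol_xyz(ligand3d)
  la <- ligand3d$atoms
  adj <- .mol_adj(ligand3d)
  # apolar ligand carbons: only C/H neighbours
  lig_c <- which(la$elem == "C")
  lig_c <- lig_c[vapply(lig_c, function(i) {
    all(la$elem[adj[[i]]] %in% c("C", "H"))
  }, TRUE)]
  # apolar receptor carbons: no N/O within covalent range in the residue
  rec_c <- which(a$elem == "C")
  polar <- which(a$elem %in% c("N", "O"))
  apolar <- vapply(rec_c, function(i) {
    same <- polar[a$resno[polar] == a$resno[i] &
                    a$chain[polar] == a$chain[i]]
    all(vapply(same, function(j) {
      .dist3(c(a$x[i], a$y[i], a$z[i]), c(a$x[j], a$y[j], a$z[j])) > 1.75
    }, TRUE))
  }, TRUE)
  rec_c <- rec_c[apolar]
  rows <- list()
  for (i in lig_c) {
    for (j in rec_c) {
      dd <- .dist3(lx[i, ], c(a$x[j], a$y[j], a$z[j]))
      if (dd <= config$hydrophobic_dist_max) {
        rows[[length(rows) + 1L]] <-
          .contact_row("hydrophobic", a, j, dd, NA_real_, i)
      }
    }
  }
  if (length(rows) == 0L) return(.empty_contacts())
  unique(do.call(rbind, rows))
}

#' @rdname detectors
#' @export
detect_halogen <- function(receptor, ligand3d,
                           config = profiler_config()) {
  a <- receptor$atoms
  lx <- .mol_xyz(ligand3d)
  la <- ligand3d$atoms
  adj <- .mol_adj(ligand3d)
  res <- .rec_residues(receptor)
  rows <- list()
  rec_pt <- function(i) c(a$x[i], a$y[i], a$z[i])
  rec_acc <- integer()
  for (ridx in res) {
    rn <- a$resid[ridx[1L]]
    acc_names <- c("O", "OXT", .REC_ACCEPTOR_ATOMS[[rn]])
    rec_acc <- c(rec_acc, ridx[a$name[ridx] %in% acc_names])
  }
  lig_x <- which(la$elem %in% c("F", "Cl", "Br", "I"))
  for (xi in lig_x) {
    cnb <- adj[[xi]][la$elem[adj[[xi]]] == "C"]
    if (length(cnb) != 1L) next
    for (acc in rec_acc) {
      apt <- rec_pt(acc)
      dd <- .dist3(lx[xi, ], apt)
      if (dd > config$halogen_dist_max) next
      don_ang <- .angle_deg(lx[cnb, ], lx[xi, ], apt)
      if (abs(don_ang - config$halogen_donor_angle) >
            config$halogen_angle_tol) next
      # acceptor-side geometry: angle at A between its bonded heavy
      # neighbour Y and the halogen
      ynb <- which(vapply(seq_len(nrow(a)), function(j) {
        j != acc && a$elem[j] != "H" && .dist3(rec_pt(j), apt) <= 1.8
      }, TRUE))
      if (length(ynb) > 0L) {
        acc_ang <- min(vapply(ynb, function(j) {
          abs(.angle_deg(rec_pt(j), apt, lx[xi, ]) -
                config$halogen_acceptor_angle)
        }, 0))
        if (acc_ang > config$halogen_angle_tol) next
        acc_ang <- config$halogen_acceptor_angle  # report the donor angle
      }
      rows[[length(rows) + 1L]] <-
        .contact_row("halogen_bond", a, acc, dd, don_ang, xi)
    }
  }
  if (length(rows) == 0L) return(.empty_contacts())
  unique(do.call(rbind, rows))
}

# centroid and unit normal of a set of coordinates (SVD plane fit)
.ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr))
  list(centroid = ctr, normal = sv$v[, 3L])
}

#' @rdname detectors
#' @export
detect_pistack <- function(receptor, ligand3d,
                           config = profiler_config()) {
  a <- receptor$atoms
  lx <- .mol_xyz(ligand3d)
  res <- .rec_residues(receptor)
  lig_rings <- .aromatic_rings(ligand3d)
  if (length(lig_rings) == 0L) return(.empty_contacts())
  rows <- list()
  for (ridx in res) {
    rn <- a$resid[ridx[1L]]
    ring_names <- .REC_RING_ATOMS[[rn]]
    if (is.null(ring_names)) next
    sel <- ridx[a$name[ridx] %in% ring_names]
    if (length(sel) < length(ring_names)) next
    rp <- .ring_plane(as.matrix(a[sel, c("x", "y", "z")]))
    for (lr in lig_rings) {
      lp <- .ring_plane(lx[lr, , drop = FALSE])
      dd <- .dist3(rp$centroid, lp$centroid)
      if (dd > config$pistack_centroid_max) next
      cosang <- abs(sum(rp$normal * lp$normal))
      ang <- acos(pmin(1, cosang)) * 180 / pi   # 0 = parallel, 90 = perp
      parallel <- ang <= config$pistack_angle_tol
      perp <- abs(90 - ang) <= config$pistack_angle_tol
      if (!parallel && !perp) next
      rows[[length(rows) + 1L]] <-
        .contact_row("pi_stack", a, sel, dd, ang, lr)
    }
  }
  if (length(rows) == 0L) return(.empty_contacts())
  unique(do.call(rbind, rows))
}

#' @rdname detectors
#' @export
detect_saltbridge <- function(receptor, ligand3d,
                              config = profiler_config()) {
  a <- receptor$atoms
  lx <- .mol_xyz(ligand3d)
  la <- ligand3d$atoms
  res <- .rec_residues(receptor)
  # ligand charged-group centroids
  lig_pos <- which(la$chg > 0L)
  lig_neg <- which(la$chg < 0L)
  rows <- list()
  for (ridx in res) {
    rn <- a$resid[ridx[1L]]
    for (sign in c("pos", "neg")) {
      grp_names <- if (sign == "pos") .REC_POS_GROUPS[[rn]]
                   else .REC_NEG_GROUPS[[rn]]
      if (is.null(grp_names)) next
      sel <- ridx[a$name[ridx] %in% grp_names]
      if (length(sel) == 0L) next
      ctr <- colMeans(as.matrix(a[sel, c("x", "y", "z")]))
      lig_grp <- if (sign == "pos") lig_neg else lig_pos
      for (i in lig_grp) {
        dd <- .dist3(ctr, lx[i, ])
        if (dd <= config$saltbridge_dist_max) {
          rows[[length(rows) + 1L]] <-
            .contact_row("salt_bridge", a, sel, dd, NA_real_, i)
        }
      }
    }
  }
  if (length(rows) == 0L) return(.empty_contacts())
  unique(do.call(rbind, rows))
}

#' Profile all contacts of one pose
#'
#' Union of the five detectors plus the pocket-shell residue list
#' (residues with any heavy atom within `shell_radius` of any ligand heavy
#' atom, extended by contact residues so that every contact's residue is
#' in the shell).
#'
#' @param receptor a `fl_receptor`.
#' @param ligand3d an `fl_mol` with coordinates.
#' @param config a [profiler_config()].
#' @return a `fl_profile`: `contacts` data.frame, `shell_residues`
#'   data.frame, `hbond_mode` (`explicit-H` or `heavy-proxy`).
#' @export
profile_pose <- function(receptor, ligand3d, config = profiler_config()) {
  if (nrow(ligand3d$atoms) == 0L) stop("empty ligand", call. = FALSE)
  if (any(!is.finite(.mol_xyz(ligand3d)))) {
    stop("ligand has non-finite coordinates", call. = FALSE)
  }
  contacts <- rbind(
    detect_hbonds(receptor, ligand3d, config),
    detect_hydrophobic(receptor, ligand3d, config),
    detect_halogen(receptor, ligand3d, config),
    detect_pistack(receptor, ligand3d, config),
    detect_saltbridge(receptor, ligand3d, config)
  )
  a <- receptor$atoms
  lx <- .mol_xyz(ligand3d)[ligand3d$atoms$elem != "H", , drop = FALSE]
  heavy <- which(a$elem != "H")
  rx <- as.matrix(a[heavy, c("x", "y", "z")])
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), `+`) - 2 * rx %*% t(lx)
  near <- heavy[apply(sqrt(pmax(d2, 0)) <= config$shell_radius, 1L, any)]
  shell <- unique(data.frame(chain = a$chain[near], resnum = a$resno[near],
                             resname = a$resid[near],
                             stringsAsFactors = FALSE))
  if (nrow(contacts) > 0L) {
    shell <- unique(rbind(shell, unique(
      contacts[, c("chain", "resnum", "resname")])))
  }
  shell <- shell[order(shell$chain, shell$resnum), , drop = FALSE]
  rownames(shell) <- NULL
  hmode <- if (any(a$elem == "H")) "explicit-H" else "heavy-proxy"
  prof <- structure(list(contacts = contacts, shell_residues = shell,
                         hbond_mode = hmode, config = config),
                    class = "fl_profile")
  if (!is.null(receptor$residue_map)) {
    prof <- apply_residue_map(prof, receptor$residue_map)
  }
  prof
}

#' @export
print.fl_profile <- function(x, ...) {
  cat("<fl_profile> ", nrow(x$contacts), " contacts (",
      paste(names(table(x$contacts$kind)), table(x$contacts$kind),
            sep = ":", collapse = ", "),
      "), shell of ", nrow(x$shell_residues), " residues\n", sep = "")
  invisible(x)
}

#' Annotate contacts with Ballesteros-Weinstein labels
#'
#' @param profile a `fl_profile`.
#' @param residue_map named character vector `resno -> label` (e.g.
#'   `c("302" = "8.48")`) or data.frame (`resno`, `bw`).
#' @param receptor optional `fl_receptor` for key validation.
#' @return the profile with `bw` filled where mapped; unmapped residues
#'   stay blank.
#' @export
apply_residue_map <- function(profile, residue_map, receptor = NULL) {
  if (is.data.frame(residue_map)) {
    residue_map <- stats::setNames(as.character(residue_map$bw),
                                   as.character(residue_map$resno))
  }
  if (!is.null(receptor)) {
    missing <- setdiff(names(residue_map),
                       as.character(receptor$atoms$resno))
    if (length(missing) > 0L) {
      stop("residue_map keys absent from the structure: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(profile$contacts) > 0L && length(residue_map) > 0L) {
    m <- residue_map[as.character(profile$contacts$resnum)]
    profile$contacts$bw <- ifelse(is.na(m), profile$contacts$bw, m)
  }
  profile
}

#' Contact prevalence over trajectory frames
#'
#' @param frames list of `list(receptor = , ligand3d = )` pairs (or a
#'   list of precomputed `fl_profile`s).
#' @param config a [profiler_config()].
#' @param predicate function taking a `fl_profile`, returning TRUE/FALSE.
#' @return fraction of frames satisfying the predicate, with the
#'   per-frame logical trail in attribute `per_frame`.
#' @export
prevalence <- function(frames, config = profiler_config(), predicate) {
  if (length(frames) == 0L) stop("no frames supplied", call. = FALSE)
  per <- vapply(frames, function(fr) {
    prof <- if (inherits(fr, "fl_profile")) fr
            else profile_pose(fr$receptor, fr$ligand3d, config)
    isTRUE(predicate(prof))
  }, TRUE)
  structure(mean(per), per_frame = per)
}

#' Predicate: hydrogen bonds to at least k residues of a set
#'
#' Convenience predicate constructor for [prevalence()] and triage
#' contact filters.
#'
#' @param resnums residue numbers of interest.
#' @param min_n minimum number of distinct residues hydrogen-bonded.
#' @param kind contact kind to count.
#' @return a predicate function over `fl_profile`s.
#' @export
pred_contacts_to <- function(resnums, min_n = 1L, kind = "hbond") {
  force(resnums); force(min_n); force(kind)
  function(profile) {
    cc <- profile$contacts
    hit <- unique(cc$resnum[cc$kind == kind & cc$resnum %in% resnums])
    length(hit) >= min_n
  }
}

#' Write a profile's contacts as CSV
#'
#' @param profile a `fl_profile`.
#' @param path output CSV.
#' @export
write_contacts <- function(profile, path) {
  utils::write.csv(profile$contacts, path, row.names = FALSE)
  invisible(path)
}
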